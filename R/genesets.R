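#' Gene set collections
#'
#' A gene set collection is a named list of sets; each set is a list with
#' an `up` component (character vector) and an optional `down` component
#' for bidirectional signatures. Up and down members must be disjoint.
#'
#' @param sets Named list. Elements may be plain character vectors
#'   (treated as `up`-only sets) or lists with `up` / `down` components.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(sets) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  if (anyDuplicated(names(sets))) stop("duplicate gene set names")
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(up = s, down = NULL)
    if (is.null(s$up) || !length(s$up)) stop("gene sets must be non-empty")
    s$up <- unique(as.character(s$up))
    if (!is.null(s$down)) {
      s$down <- unique(as.character(s$down))
      if (length(intersect(s$up, s$down)))
        stop("up and down members of a set must be disjoint")
    }
    s[c("up", "down")]
  })
  structure(sets, class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets\n", length(x)))
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set name, description, then member genes. All
#' sets are read as unidirectional (`up`) sets.
#'
#' @param path Path to a GMT file.
#' @return A `geneset_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >=1 gene): ", path)
    parts[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  geneset_collection(sets)
}

#' Write gene sets to a GMT file
#'
#' Only the `up` members are written (GMT has no direction field); sets
#' with a `down` component are written as two lines suffixed `_UP` and
#' `_DN`.
#'
#' @param sets A `geneset_collection`.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "geneset_collection"))
  lines <- character(0)
  for (nm in names(sets)) {
    s <- sets[[nm]]
    if (is.null(s$down)) {
      lines <- c(lines, paste(c(nm, "na", s$up), collapse = "\t"))
    } else {
      lines <- c(lines,
                 paste(c(paste0(nm, "_UP"), "na", s$up), collapse = "\t"),
                 paste(c(paste0(nm, "_DN"), "na", s$down), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
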