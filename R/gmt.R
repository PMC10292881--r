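#' Read a gene-set library in GMT format
#'
#' One set per tab-separated line: name, description (discarded), then
#' member genes. Duplicate members within a line are collapsed; duplicate
#' set names across lines are an error.
#'
#' @param path GMT file.
#' @return A named list of character vectors of class `geneset_library`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need name, description, >=1 member",
                   i, length(f)))
    nm[i] <- f[1]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop(sprintf("GMT line %d: empty member set", i))
    sets[[i]] <- members
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    stop("duplicated gene-set name(s): ", paste(dup, collapse = ", "))
  names(sets) <- nm
  structure(sets, class = "geneset_library")
}

#' Write a gene-set library to GMT
#'
#' @param library Named list of character vectors (or `geneset_library`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  if (is.null(names(library)) || any(!nzchar(names(library))))
    stop("all gene sets must be named")
  lines <- vapply(names(library), function(nm) {
    paste(c(nm, "na", library[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.geneset_library <- function(x, ...) {
  sizes <- lengths(x)
  cat(sprintf("<geneset_library> %d sets, member counts %d-%d\n",
              length(x), min(sizes), max(sizes)))
  invisible(x)
}
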