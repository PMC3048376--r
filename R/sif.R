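#' Read a signed network from a SIF file
#'
#' The expected dialect is three whitespace- or tab-delimited columns per
#' line: `source sign target`, with sign 1 (activation) or -1 (inhibition).
#' Empty lines and lines starting with `#` are ignored. Duplicate records
#' are collapsed to a single edge.
#'
#' @param path path to the SIF file.
#' @param stimuli,inhibited,measured optional role assignments passed to
#'   [cfl_pkn()] (roles are usually assigned later from a dataset via
#'   [designate_roles()]).
#' @return a `cfl_pkn`.
#' @export
read_sif <- function(path, stimuli = character(), inhibited = character(),
                     measured = character()) {
  if (!file.exists(path)) stop("SIF file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  recs <- lapply(which(keep), function(i) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(fields) != 3L) {
      stop(sprintf("malformed SIF line %d: expected 3 fields, got %d",
                   i, length(fields)), call. = FALSE)
    }
    sgn <- suppressWarnings(as.integer(fields[2]))
    if (is.na(sgn) || !sgn %in% c(-1L, 1L)) {
      stop(sprintf("SIF line %d: sign '%s' is not 1 or -1", i, fields[2]),
           call. = FALSE)
    }
    data.frame(source = fields[1], sign = sgn, target = fields[3],
               stringsAsFactors = FALSE)
  })
  edges <- if (length(recs)) do.call(rbind, recs) else
    data.frame(source = character(), sign = integer(), target = character())
  cfl_pkn(edges, stimuli = stimuli, inhibited = inhibited, measured = measured)
}

#' Write a PKN to a SIF file
#'
#' Inverse of [read_sif()]: re-reading the written file reproduces the node
#' and edge sets exactly. Role flags are not part of SIF and are not
#' written.
#'
#' @param pkn a `cfl_pkn`.
#' @param path output path.
#' @export
write_sif <- function(pkn, path) {
  stopifnot(inherits(pkn, "cfl_pkn"))
  lines <- if (nrow(pkn$edges)) {
    paste(pkn$edges$source, pkn$edges$sign, pkn$edges$target, sep = "\t")
  } else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
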