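#' Perturbation-response dataset
#'
#' Container for an experimental design (stimulus values and inhibitor
#' flags, one row per condition) plus observed node activities normalized to
#' \[0,1\], with missing values allowed.
#'
#' @param stimuli data.frame of stimulus values in \[0,1\]; columns named by
#'   stimulus node.
#' @param inhibitors data.frame of inhibitor flags in \{0,1\}; columns named
#'   by inhibited node. May have zero columns.
#' @param obs numeric matrix (conditions x measured nodes) of observed
#'   activities in \[0,1\] or NA.
#' @param da optional data.frame of acquisition times, carried for
#'   provenance only.
#' @return object of class `cfl_dataset`.
#' @export
cfl_dataset <- function(stimuli, inhibitors = NULL, obs, da = NULL) {
  stimuli <- as.data.frame(stimuli)
  if (is.null(inhibitors)) {
    inhibitors <- data.frame(row.names = seq_len(nrow(stimuli)))
  }
  inhibitors <- as.data.frame(inhibitors)
  if (ncol(inhibitors) == 0) {
    inhibitors <- data.frame(row.names = seq_len(nrow(stimuli)))
  }
  obs <- as.matrix(obs)
  storage.mode(obs) <- "double"
  n <- nrow(stimuli)
  stopifnot(nrow(inhibitors) == n, nrow(obs) == n)
  vals <- unlist(stimuli)
  if (length(vals) && any(vals < 0 | vals > 1, na.rm = TRUE)) {
    stop("stimulus values outside [0,1]", call. = FALSE)
  }
  iv <- unlist(inhibitors)
  if (length(iv) && !all(iv %in% c(0, 1))) {
    stop("inhibitor flags must be 0 or 1", call. = FALSE)
  }
  if (any(obs < -1e-9 | obs > 1 + 1e-9, na.rm = TRUE)) {
    stop("observed values outside [0,1]", call. = FALSE)
  }
  key <- apply(cbind(stimuli, inhibitors), 1, paste, collapse = "|")
  if (anyDuplicated(key)) {
    stop("duplicate treatment/inhibitor combinations in the design",
         call. = FALSE)
  }
  structure(list(stimuli = stimuli, inhibitors = inhibitors, obs = obs,
                 da = da), class = "cfl_dataset")
}

#' @export
print.cfl_dataset <- function(x, ...) {
  cat(sprintf("cFL dataset: %d conditions, %d stimuli, %d inhibitors, %d signals (%d observations)\n",
              nrow(x$stimuli), ncol(x$stimuli), ncol(x$inhibitors),
              ncol(x$obs), n_obs(x)))
  invisible(x)
}

#' Number of non-missing observations
#' @param dataset a `cfl_dataset`.
#' @return integer count of non-missing value cells.
#' @export
n_obs <- function(dataset) sum(!is.na(dataset$obs))

#' @export
dim.cfl_dataset <- function(x) dim(x$obs)

#' Read a MIDAS-dialect CSV dataset
#'
#' Column roles are declared in the header: `TR:<node>` a stimulus value in
#' \[0,1\], `TR:<node>:i` an inhibitor flag in \{0,1\}, `DV:<node>` a
#' measured value in \[0,1\] or `NA`, `DA:<node>` an acquisition time (kept
#' for provenance, ignored by modeling). One row per experimental condition.
#'
#' @param path path to the CSV file (UTF-8, comma separated, header row
#'   mandatory).
#' @return a `cfl_dataset`.
#' @export
read_midas <- function(path) {
  if (!file.exists(path)) stop("MIDAS file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, na.strings = "NA",
                         fileEncoding = "UTF-8")
  cn <- names(tab)
  is_inhib <- grepl("^TR:.+:i$", cn)
  is_stim <- grepl("^TR:", cn) & !is_inhib
  is_dv <- grepl("^DV:", cn)
  is_da <- grepl("^DA:", cn)
  unknown <- cn[!(is_inhib | is_stim | is_dv | is_da)]
  if (length(unknown)) {
    stop("unknown MIDAS column prefix in: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  strip <- function(x, pat, rep = "") sub(pat, rep, x)
  stim <- tab[, is_stim, drop = FALSE]
  names(stim) <- strip(names(stim), "^TR:")
  inhib <- tab[, is_inhib, drop = FALSE]
  names(inhib) <- strip(strip(names(inhib), "^TR:"), ":i$")
  dv <- as.matrix(tab[, is_dv, drop = FALSE])
  colnames(dv) <- strip(colnames(dv), "^DV:")
  bad <- which(dv < 0 | dv > 1, arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad))) {
    stop(sprintf("value outside [0,1] at row %d, signal '%s'",
                 bad[1, 1], colnames(dv)[bad[1, 2]]), call. = FALSE)
  }
  da <- if (any(is_da)) {
    d <- tab[, is_da, drop = FALSE]
    names(d) <- strip(names(d), "^DA:")
    d
  } else NULL
  cfl_dataset(stim, inhib, dv, da = da)
}

#' Write a dataset as MIDAS-dialect CSV
#'
#' Inverse of [read_midas()]: design, observations and missingness
#' round-trip exactly (missing cells written as `NA`).
#'
#' @param dataset a `cfl_dataset`.
#' @param path output path.
#' @export
write_midas <- function(dataset, path) {
  stopifnot(inherits(dataset, "cfl_dataset"))
  out <- data.frame(row.names = seq_len(nrow(dataset$stimuli)))
  for (nm in colnames(dataset$stimuli)) {
    out[[paste0("TR:", nm)]] <- dataset$stimuli[[nm]]
  }
  for (nm in colnames(dataset$inhibitors)) {
    out[[paste0("TR:", nm, ":i")]] <- dataset$inhibitors[[nm]]
  }
  if (!is.null(dataset$da)) {
    for (nm in colnames(dataset$da)) out[[paste0("DA:", nm)]] <- dataset$da[[nm]]
  }
  for (nm in colnames(dataset$obs)) {
    out[[paste0("DV:", nm)]] <- dataset$obs[, nm]
  }
  utils::write.csv(out, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Conditions of a dataset as clamp assignments
#'
#' Internal helper shared by simulation and training: builds the per-node
#' clamp matrix (nodes x conditions) in which stimulus nodes carry their
#' design value, inhibited nodes with flag 1 are clamped to 0, and all other
#' entries are NA (free).
#' @keywords internal
.clamp_matrix <- function(nodes, stimuli, inhibitors) {
  n_cond <- nrow(stimuli)
  cl <- matrix(NA_real_, length(nodes), n_cond, dimnames = list(nodes, NULL))
  for (nm in colnames(stimuli)) cl[nm, ] <- stimuli[[nm]]
  for (nm in colnames(inhibitors)) {
    on <- inhibitors[[nm]] == 1
    cl[nm, on] <- 0
  }
  cl
}
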