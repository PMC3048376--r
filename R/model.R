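#' Decode a discrete genome into a cFL model
#'
#' A genome carries one integer allele in 0..7 per slot of the hypothesis
#' space. Allele 0 means the slot is absent; alleles 1..7 index the slot's
#' library (linear library for stimulus-sourced slots, Hill library
#' otherwise), in the fixed order of [tf_library()].
#'
#' @param genome integer vector of length `hs$h` with values in 0..7.
#' @param hs a `cfl_hypothesis`.
#' @return an object of class `cfl_model`, stage `"discrete"`.
#' @export
decode <- function(genome, hs) {
  stopifnot(inherits(hs, "cfl_hypothesis"))
  genome <- as.integer(genome)
  if (length(genome) != hs$h) {
    stop(sprintf("genome length %d != slot count %d", length(genome), hs$h),
         call. = FALSE)
  }
  if (any(genome < 0L | genome > hs$a)) {
    stop("allele out of range 0..", hs$a, call. = FALSE)
  }
  lin <- hs$slots$library == "linear"
  type <- integer(hs$h)
  p1 <- numeric(hs$h)
  p2 <- numeric(hs$h)
  on <- genome > 0L
  type[on & lin] <- 1L
  type[on & !lin] <- 2L
  lin_lib <- seq(0.2, 0.8, by = 0.1)
  hill_n <- c(1.01, rep(3, 6))
  hill_k <- c(68.5098, seq(0.2, 0.7, by = 0.1))
  sel <- which(on & lin)
  p1[sel] <- lin_lib[genome[sel]]
  sel <- which(on & !lin)
  p1[sel] <- hill_n[genome[sel]]
  p2[sel] <- hill_k[genome[sel]]
  new_cfl_model(hs, genome = genome, type = type, p1 = p1, p2 = p2,
                stage = "discrete")
}

# internal constructor; type 0 absent / 1 linear (p1 slope) / 2 hill (p1 n,
# p2 k)
new_cfl_model <- function(hs, genome = NULL, type, p1, p2,
                          stage = "discrete", mse = NA_real_, seed = NA_integer_) {
  structure(list(hypothesis = hs, genome = genome,
                 type = as.integer(type), p1 = as.numeric(p1),
                 p2 = as.numeric(p2), stage = stage,
                 mse = mse, seed = seed),
            class = "cfl_model")
}

#' @export
print.cfl_model <- function(x, ...) {
  ag <- active_gates(x)
  cat(sprintf("cFL model (stage %s): %d/%d gates active, %d parameters",
              x$stage, length(ag), x$hypothesis$w, parameter_count(x)))
  if (!is.na(x$mse)) cat(sprintf(", MSE = %.4g", x$mse))
  cat("\n")
  for (gi in ag) {
    g <- x$hypothesis$gates[[gi]]
    terms <- vapply(seq_len(nrow(g$inputs)), function(i) {
      s <- g$slots[i]
      par <- if (x$type[s] == 1L) sprintf("linear %.3g", x$p1[s])
             else sprintf("hill n=%.3g k=%.3g", x$p1[s], x$p2[s])
      sprintf("%s%s [%s]", if (g$inputs$sign[i] < 0) "!" else "",
              g$inputs$node[i], par)
    }, "")
    cat(sprintf("  %s <- %s\n", g$output, paste(terms, collapse = " AND ")))
  }
  invisible(x)
}

#' Active gates of a model
#'
#' A gate is active iff none of its slots is absent; an AND gate with any
#' absent slot is wholly inactive.
#'
#' @param model a `cfl_model`.
#' @return integer indices into the hypothesis space's gate list.
#' @export
active_gates <- function(model) {
  hs <- model$hypothesis
  which(vapply(hs$gates, function(g) all(model$type[g$slots] != 0L), TRUE))
}

#' Number of fitted transfer-function parameters
#'
#' Counts 2 parameters (n, k) per active Hill slot and 1 (slope) per active
#' linear slot; slots of inactive gates count 0.
#'
#' @param model a `cfl_model`.
#' @return integer parameter count.
#' @export
parameter_count <- function(model) {
  act <- unlist(lapply(model$hypothesis$gates[active_gates(model)], `[[`, "slots"))
  if (!length(act)) return(0L)
  sum(ifelse(model$type[act] == 2L, 2L, 1L))
}

# transfer spec of one slot as a cfl_tf, or NULL if absent
slot_spec <- function(model, s) {
  if (model$type[s] == 0L) return(NULL)
  if (model$type[s] == 1L) tf_linear(model$p1[s]) else tf_hill(model$p1[s], model$p2[s])
}

# deactivate the given gates (set all their slots absent)
deactivate_gates <- function(model, gates) {
  for (gi in gates) {
    sl <- model$hypothesis$gates[[gi]]$slots
    model$type[sl] <- 0L
    model$p1[sl] <- 0
    model$p2[sl] <- 0
  }
  model$genome <- NULL  # topology no longer matches any single genome
  model
}
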