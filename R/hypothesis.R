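#' Expand a compressed PKN into a cFL hypothesis space
#'
#' For every node with incoming edges the expansion enumerates candidate
#' logic gates. In `all_pairs` mode each incoming edge yields a 1-input gate
#' (activating or inhibitory) and every unordered pair of incoming edges
#' yields a 2-input AND gate. In `inhibitory_only` mode only activating
#' edges yield standalone gates and AND gates are restricted to
#' (activating, inhibitory) pairs, encoding "A AND NOT B": a standalone
#' inhibitory gate would make the output active precisely when its input is
#' not, which is rarely a meaningful signaling hypothesis.
#'
#' Each (gate, input) pair owns one discrete transfer-function slot. Slots
#' whose input node is a stimulus draw from the linear library, all others
#' from the Hill library (see [tf_library()]).
#'
#' @param pkn a compressed `cfl_pkn` with roles designated.
#' @param mode expansion mode, `"all_pairs"` or `"inhibitory_only"`.
#' @return an object of class `cfl_hypothesis` with elements `pkn`, `mode`,
#'   `gates` (list of gates, each with `output`, `inputs` data.frame and
#'   `slots` indices), `slots` (data.frame of slot metadata), `w` (gate
#'   count), `h` (slot count) and `a` (library size per slot, 7).
#' @export
expand_pkn <- function(pkn, mode = c("all_pairs", "inhibitory_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pkn, "cfl_pkn"))
  gates <- list()
  for (out in pkn$nodes) {
    ins <- pkn$edges[pkn$edges$target == out, , drop = FALSE]
    if (nrow(ins) == 0) next
    ins <- ins[order(ins$source, ins$sign), , drop = FALSE]
    act <- ins[ins$sign == 1, , drop = FALSE]
    inh <- ins[ins$sign == -1, , drop = FALSE]
    g <- list()
    one_input <- function(row) {
      list(output = out,
           inputs = data.frame(node = row$source, sign = row$sign,
                               stringsAsFactors = FALSE))
    }
    two_input <- function(r1, r2) {
      inp <- data.frame(node = c(r1$source, r2$source),
                        sign = c(r1$sign, r2$sign), stringsAsFactors = FALSE)
      inp <- inp[order(inp$node, inp$sign), , drop = FALSE]
      list(output = out, inputs = inp)
    }
    if (mode == "all_pairs") {
      for (i in seq_len(nrow(ins))) g[[length(g) + 1L]] <- one_input(ins[i, ])
      if (nrow(ins) >= 2) {
        for (i in seq_len(nrow(ins) - 1)) {
          for (j in seq(i + 1, nrow(ins))) {
            if (ins$source[i] == ins$source[j]) next  # same node twice
            g[[length(g) + 1L]] <- two_input(ins[i, ], ins[j, ])
          }
        }
      }
    } else {
      for (i in seq_len(nrow(act))) g[[length(g) + 1L]] <- one_input(act[i, ])
      for (i in seq_len(nrow(act))) {
        for (j in seq_len(nrow(inh))) {
          if (act$source[i] == inh$source[j]) next
          g[[length(g) + 1L]] <- two_input(act[i, ], inh[j, ])
        }
      }
      if (length(g) == 0 && nrow(inh) > 0) {
        warning(sprintf("node '%s' has only inhibitory inputs: no candidate gates in inhibitory_only mode",
                        out), call. = FALSE)
      }
    }
    gates <- c(gates, g)
  }
  # stable order: by output, then arity, then input names
  ord <- order(vapply(gates, `[[`, "", "output"),
               vapply(gates, function(g) nrow(g$inputs), 0L),
               vapply(gates, function(g) paste(g$inputs$node, collapse = "&"), ""))
  gates <- gates[ord]
  slot_rows <- list()
  s <- 0L
  for (gi in seq_along(gates)) {
    inp <- gates[[gi]]$inputs
    idx <- s + seq_len(nrow(inp))
    gates[[gi]]$slots <- idx
    s <- s + nrow(inp)
    slot_rows[[gi]] <- data.frame(
      slot = idx, gate = gi, output = gates[[gi]]$output,
      input = inp$node, sign = inp$sign,
      library = ifelse(inp$node %in% pkn$stimuli, "linear", "hill"),
      stringsAsFactors = FALSE)
  }
  slots <- if (length(slot_rows)) do.call(rbind, slot_rows) else
    data.frame(slot = integer(), gate = integer(), output = character(),
               input = character(), sign = integer(), library = character())
  slots$id <- sprintf("%s|%d|%s", slots$output, slots$gate, slots$input)
  hs <- structure(list(pkn = pkn, mode = mode, gates = gates, slots = slots,
                       w = length(gates), h = nrow(slots), a = 7L),
                  class = "cfl_hypothesis")
  hs$compiled <- .compile_hypothesis(hs)
  hs
}

# integer arrays consumed by the C++ simulator (0-based indices)
.compile_hypothesis <- function(hs) {
  nodes <- hs$pkn$nodes
  node_idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  gate_output <- vapply(hs$gates, function(g) node_idx[[g$output]], 0L)
  gate_len <- vapply(hs$gates, function(g) nrow(g$inputs), 0L)
  gate_start <- cumsum(c(0L, gate_len))[seq_along(gate_len)]
  list(n_nodes = length(nodes), nodes = nodes,
       gate_output = as.integer(gate_output),
       gate_start = as.integer(gate_start),
       gate_len = as.integer(gate_len),
       slot_input = as.integer(node_idx[hs$slots$input]),
       slot_sign = as.integer(hs$slots$sign))
}

#' @export
print.cfl_hypothesis <- function(x, ...) {
  cat(sprintf("cFL hypothesis space (%s mode): %d gates, %d slots, alphabet %d\n",
              x$mode, x$w, x$h, x$a + 1L))
  cat(sprintf("  discrete search space: %d^%d = 10^%.1f genomes\n",
              x$a + 1L, x$h, x$h * log10(x$a + 1L)))
  invisible(x)
}

#' Size of the discrete search space
#'
#' Returns the gate count `w`, slot count `h` and per-slot alphabet size
#' `1 + a` (7 transfer functions plus "absent" under the default
#' libraries). The number of distinct genomes is `(1 + a)^h`.
#'
#' @param hs a `cfl_hypothesis`.
#' @return list with `w`, `h`, `alphabet_size`, and `log10_size`.
#' @export
count_search_space <- function(hs) {
  stopifnot(inherits(hs, "cfl_hypothesis"))
  list(w = hs$w, h = hs$h, alphabet_size = hs$a + 1L,
       log10_size = hs$h * log10(hs$a + 1L))
}
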