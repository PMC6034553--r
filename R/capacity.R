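#' Storage-capacity inputs for the two-layer neuron abstraction
#'
#' @param s total number of excitatory synapses
#' @param m number of independent non-linear dendritic subunits
#' @param d number of distinct input lines; defaults to s/5 (five synaptic
#'   contacts per axonal connection)
#' @return a list with `s`, `m`, `d` and `k = s/m` (synapses per subunit,
#'   real-valued)
#' @export
capacity_inputs <- function(s, m, d = s / 5) {
  stopifnot(s >= m, m >= 1, d >= 1)
  list(s = s, m = m, d = d, k = s / m)
}

# log2 of the binomial coefficient C(a, b), generalised to real arguments via
# the log-gamma function
.log2_choose <- function(a, b) (lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)) / log(2)

#' Two-layer storage capacity (bits)
#'
#' The combinatorial capacity of a neuron abstracted as m independent
#' non-linear subunits of k = s/m synapses each, drawing from d distinct
#' input lines: B2 = 2 * m * log2 C(d + k - 1, k). Non-integer k is handled
#' by log-gamma continuation of the binomial.
#'
#' @param inp a [capacity_inputs()] list
#' @return capacity in bits
#' @export
two_layer_capacity <- function(inp) {
  if (inp$k < 1) stop("domain error: need at least one synapse per subunit")
  2 * inp$m * .log2_choose(inp$d + inp$k - 1, inp$k)
}

#' One-layer storage capacity (bits)
#'
#' The same combinatorial bound with the whole cell as a single linear unit:
#' B1 = 2 * log2 C(d + s - 1, s).
#'
#' @param s total number of synapses (>= 1)
#' @param d number of distinct input lines (>= 1)
#' @return capacity in bits
#' @export
one_layer_capacity <- function(s, d) {
  stopifnot(s >= 1, d >= 1)
  2 * .log2_choose(d + s - 1, s)
}
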