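#' Izhikevich neuron parameter set
#'
#' Construct a validated 9-parameter Izhikevich model (IM) parameter set.
#' The quadratic membrane equation is
#' \deqn{C\,dv/dt = k (v - V_r)(v - V_t) - u + I}
#' \deqn{du/dt = a (b (v - V_r) - u)}
#' with a spike recorded when \eqn{v \ge V_{peak}}, followed by the reset
#' \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d}.
#'
#' @param C cell capacitance (pF), positive.
#' @param k quadratic gain (nS/mV), positive.
#' @param Vr resting potential (mV).
#' @param Vt threshold potential (mV), must exceed `Vr`.
#' @param a recovery rate (1/ms).
#' @param b recovery sensitivity (nS); may be negative (e.g. CA1 pyramidal).
#' @param Vpeak spike cutoff (mV), must exceed `Vt`.
#' @param c post-spike reset value, also called `V_min` (mV); below `Vpeak`.
#' @param d post-spike recovery increment (pA).
#' @param name optional neuron-type label.
#' @return An object of class `neuron_params` (named list).
#' @export
#' @examples
#' np <- neuron_params(C = 118, k = 0.62, Vr = -58.53, Vt = -43.52,
#'                     a = 0.005, b = 11.69, Vpeak = 11.48, c = -49.52, d = 0)
neuron_params <- function(C, k, Vr, Vt, a, b, Vpeak, c, d, name = NULL) {
  p <- list(C = C, k = k, Vr = Vr, Vt = Vt, a = a, b = b,
            Vpeak = Vpeak, c = c, d = d, name = name)
  vals <- unlist(p[c("C", "k", "Vr", "Vt", "a", "b", "Vpeak", "c", "d")])
  if (!all(is.finite(vals)))
    stop("neuron_params: all nine IM parameters must be finite numbers")
  if (C <= 0) stop("neuron_params: capacitance C must be positive")
  if (k <= 0) stop("neuron_params: quadratic gain k must be positive")
  if (Vr >= Vt) stop("neuron_params: requires Vr < Vt")
  if (Vpeak <= Vt) stop("neuron_params: requires Vpeak > Vt")
  if (c >= Vpeak) stop("neuron_params: reset c must lie below Vpeak")
  class(p) <- "neuron_params"
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("Izhikevich parameters",
      if (!is.null(x$name)) paste0("[", x$name, "]"), "\n")
  cat(sprintf("  C=%g pF  k=%g nS/mV  Vr=%g mV  Vt=%g mV\n", x$C, x$k, x$Vr, x$Vt))
  cat(sprintf("  a=%g /ms  b=%g nS  Vpeak=%g mV  c=%g mV  d=%g pA\n",
              x$a, x$b, x$Vpeak, x$c, x$d))
  invisible(x)
}

# Neuron-type table: IM parameters and default population counts.
# Interneuron counts rise to 1200 each for the large grid-scale preset.
.neuron_table <- data.frame(
  name  = c("MEC LII Stellate", "EC LI-II Multipolar Pyramidal",
            "CA1 Pyramidal", "EC LII Axo-Axonic", "MEC LII Basket",
            "EC LII Basket Multipolar"),
  role  = c("grid", "conjunctive", "place",
            "interneuron", "interneuron", "interneuron"),
  count = c(1600, 1600, 1600, 834, 833, 833),
  C     = c(118, 375, 530, 20, 20, 20),
  k     = c(0.62, 0.37, 1.74, 1, 1, 1),
  Vr    = c(-58.53, -70.53, -69.98, -55, -55, -55),
  Vt    = c(-43.52, -39.99, -57.43, -40, -40, -40),
  a     = c(0.005, 0.001, 0.003, 0.15, 0.15, 0.15),
  b     = c(11.69, 0.01, -0.782, 8, 8, 8),
  Vpeak = c(11.48, 3.96, 24.45, 25, 25, 25),
  c     = c(-49.52, -54.95, -60.35, -55, -55, -55),
  d     = c(0, 7, 25, 200, 200, 200),
  stringsAsFactors = FALSE
)

#' Default neuron-type parameter table
#'
#' The six modelled neuron types with their IM constants and default
#' population counts: MEC LII stellate cells (grid cells), EC LI-II
#' multipolar pyramidal cells (conjunctive speed-by-direction cells),
#' CA1 pyramidal cells (place cells), and three fast-spiking
#' parvalbumin-type interneuron classes (axo-axonic, basket, basket
#' multipolar) sharing standard fast-spiking constants.
#'
#' @param type optional neuron-type name; if given, returns that row as a
#'   [neuron_params] object instead of the whole table.
#' @return A data frame (or a `neuron_params` when `type` is given).
#' @export
#' @examples
#' default_neuron_params()$name
#' default_neuron_params("MEC LII Stellate")
default_neuron_params <- function(type = NULL) {
  if (is.null(type)) return(.neuron_table)
  i <- match(type, .neuron_table$name)
  if (is.na(i))
    stop("unknown neuron type '", type, "'; see default_neuron_params()$name")
  r <- .neuron_table[i, ]
  neuron_params(r$C, r$k, r$Vr, r$Vt, r$a, r$b, r$Vpeak, r$c, r$d, name = r$name)
}
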