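# Shared fixtures: demonstration circuits for the three feedback classes,
# chosen a priori inside the regime the theory assumes (bursty expression,
# p/q >> 1, regulatory function saturating in the fitted tail window) and
# with exact |eta_f| large enough to be resolvable from 1e4 cells.

constant_rf <- function(cc) {
  force(cc)
  regulatory_function(function(x) rep_len(cc, length(x)), "none",
                      s = cc, r = cc)
}

# no feedback: constant c = 8, p = 0.9 (mean ~72)
class_none <- function() list(rf = constant_rf(8), p = 0.9, d = 1)

# negative feedback: steep repressive Hill saturating at r = 1 (mean ~260)
class_negative <- function()
  list(rf = hill_regulatory_function(1e8, 30, 1, 4), p = 0.99, d = 1)

# positive feedback: increasing Hill saturating at r = 1 (mean ~52)
class_positive <- function()
  list(rf = hill_regulatory_function(2000, 0.3, 1, 2), p = 0.99, d = 1)

class_circuit <- function(topology)
  switch(topology, none = class_none(), negative = class_negative(),
         positive = class_positive())

# linear fast-switching regulatory forms of the (mean, noise) scatter
linear_activation_rf <- function(a, b, s, r)
  regulatory_function(function(x) (a * x * s + b * r) / (a * x + b),
                      "positive", s = s, r = r)

linear_inactivation_rf <- function(a, b, s, r)
  regulatory_function(function(x) (a * s + b * x * r) / (a + b * x),
                      "negative", s = s, r = r)

# small representative circuits for simulation-versus-theory checks
bursty_test_circuits <- function() list(
  list(rf = constant_rf(5), p = 0.5),
  list(rf = hill_regulatory_function(50, 20, 1, 2), p = 0.4),
  list(rf = hill_regulatory_function(30, 15, 0.5, 4), p = 0.5),
  list(rf = linear_activation_rf(2, 20, 6, 1), p = 0.3),
  list(rf = hill_regulatory_function(100, 10, 2, 1), p = 0.6))

# full-chain circuits in the fast-switching, lambda = 30 regime
# (switching rates scaled x50 above the per-unit event scale)
full_test_circuits <- function() {
  mk <- function(s, r, p, sw) {
    v <- 30
    gene_circuit(s = s, r = r, u = v * p / (1 - p), v = v, d = 1,
                 switching = sw)
  }
  list(
    mk(8, 1, 0.5, switching_spec("constant", a = 250, b = 250)),
    mk(10, 1, 0.5, switching_spec("hill", a = 2000, h = 2)),
    mk(8, 0.5, 0.6, switching_spec("linear_inactivation",
                                   a = 400, b = 100, k = 25)),
    mk(12, 2, 0.4, switching_spec("linear_activation",
                                  a = 100, b = 300, k = 15)),
    mk(6, 1, 0.7, switching_spec("constant", a = 100, b = 400)))
}
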