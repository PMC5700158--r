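# fbnoise

Infer the feedback sign of a gene circuit — positive, negative, or none —
from the shape of its single-cell protein distribution.

## The problem

A gene regulated by its own product reaches similar-looking, usually
unimodal steady-state expression distributions whether the autoregulation
is positive, negative, or absent, so the topology cannot be read off the
histogram by eye. It can, however, be read off three *digital features*
of that histogram. For the standard three-stage expression model
(promoter switching between an active form transcribing at rate `s` and
an inactive form at basal rate `r`, translation `u`, mRNA decay `v`,
protein decay `d`) with fast switching and bursty translation
(`p = u/(u+v)`, `q = 1 - p`, mean burst size `p/q`), the protein noise
`η = σ²/⟨n⟩²` decomposes **exactly** as

    η = 1/(q⟨n⟩) + η_f,        η_f = Cov(n, c_n) / (⟨n⟩⟨c_n⟩)

where `c_n = (a_n s + b_n r)/(a_n + b_n)` is the effective transcription
rate at protein count `n`. The sign of the feedback coefficient `η_f` is
the sign of the feedback. Since `q` is also the exponential decay rate of
the distribution's tail, everything on the right is measurable from
single-cell data:

    η_f = σ²/⟨n⟩² − 1/(q⟨n⟩)

with `⟨n⟩`, `σ²` from sample moments and `q` from a tail fit. The package
implements the exact stationary law of the bursty model (for arbitrary
nonlinear regulation), this decomposition, the bounds on noise
suppression by negative feedback
(`1/(q⟨n⟩) · 1/(1+αp/dq) ≤ η < 1/(q⟨n⟩)`, with `α` the steepness of the
regulatory function and `γ = −η_f/(η−η_f) ≤ 1/(1+dq/αp)` the filter
efficiency), exact Gillespie simulators for the full chain and the
reduced bursty model, the bootstrap inference pipeline, and a synthetic
dose–response generator emulating an inducer-tunable negative-feedback
reporter next to an unregulated control.

It is aimed at people analyzing flow-cytometry or imaging snapshots of
reporter expression (counts or arbitrary-unit fluorescence — the method
is scale invariant) and at modelers studying noise in autoregulatory
circuits.

## Worked example

A strongly repressed gene (`c(x) = (as + x⁴r)/(a + x⁴)`, `a = 1e8`,
`s = 30`, `r = 1`, bursty with `p = 0.99`, rates in units of the protein
decay rate):

```r
library(fbnoise)
rf   <- hill_regulatory_function(a = 1e8, s = 30, r = 1, h = 4)
dist <- steady_state_distribution(rf, p = 0.99, d = 1)
decompose_noise(dist, rf, burst_parameters(u = 99 * 30, v = 30, d = 1),
                d = 1, v = 30)
#> Noise decomposition
#>   mean <n> = 263.41, var = 11865, eta = 0.17099
#>   Poisson 1/<n> = 0.0037963, mRNA d/(v<m>) = 0.37583
#>   feedback-free 1/(q<n>) = 0.37963, feedback eta_f = -0.20864
```

The total noise (0.171) is less than half the feedback-free noise
(0.380): the loop removes `γ = −η_f/(η−η_f) = 0.55` — 55% — of the noise
it could act on. Now pretend we only had 10⁴ sampled cells:

```r
cells <- sample_cells(dist, 1e4, seed = 1, label = "demo")
infer_feedback(cells, seed = 1)
#> Feedback inference 'demo' (10000 cells)
#>   mean = 265.31, var = 12263, eta = 0.17422
#>   q_hat = 0.009805 (tail R^2 = 0.802, 646 bins)
#>   feedback-free 1/(q<n>) = 0.38442
#>   eta_f = -0.2102 +/- 0.0365 (z = -5.75) -> call: NEGATIVE
```

The tail fit recovers `q̂ ≈ 0.0098` (truth: 0.01), the estimated feedback
coefficient −0.21 ± 0.04 matches the exact −0.209, and the circuit is
called negative at `z = −5.8`. See the methods vignette
(`vignettes/feedback-noise-inference.Rmd`) for the estimator's validity
regime and every default.

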