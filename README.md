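# wtabright

Simulation of how surrounding context — backgrounds and bright distractor
squares — modulates early visual cortical responses and the perceived
brightness of a gray target, using a two-layer stochastic
k-winner-take-all (k-WTA) spiking network.

The package is aimed at computational-neuroscience users who want a small,
fully reproducible model of contextual brightness effects: simultaneous
brightness contrast (the same gray patch looks lighter on a dark
background), and the darkening of a target by distractors that are closer,
lighter, or bigger.

## The model in brief

* **Afferents.** 900 Difference-of-Gaussians filters
  `f_n(x) = exp(-|x-x_n|²/σ_c²) - φ exp(-|x-x_n|²/σ_s²)` tile a 60×60
  image on a 2-px grid; rectified, divisively normalized responses drive
  Bernoulli spikes (≤ 1/ms) that are filtered into double-exponential
  synaptic traces `ε(Δ) = e^(-Δ/10) - e^(-Δ/1)`.
* **Circuit.** K excitatory neurons spike with probability
  `logistic(u_k)`, `u_k = Σ w_kn x̃_n + Σ v_kk' z̃_k' - v^EI Σ ỹ_j + b_k`,
  with absolute refractoriness; J rate-based inhibitory neurons
  (rectified drive, Poisson-discretized spikes) enforce sparse
  competition.
* **Learning.** At each timestep the binary response vector is identified
  against per-stimulus FIFO clustering sets via bootstrap energy
  distances; a correct identification yields reward, which converts
  discounted eligibility traces
  `E ← γE + z_t (x̃_t - h(W))`, `h(w) = 1 - 1/w + 1/(e^w - 1)`,
  into clipped weight updates (an online EM step).
* **Readout.** Brightness perception is the image reconstruction
  `I_rec(x) = Σ_kn z̄_k w_kn x̄_n a_n f_n(x)` from averaged testing
  responses; compared images share one pooled mean/SD normalization.
  Contextual modulation is measured by CMI = (r₁-r₂)/(r₁+r₂) histograms
  and zero-lag cross-correlation differences.

See `vignettes/brightness-network.Rmd` for the full model description,
the calibration of every open constant, and known limitations.

## Worked example

```r
library(wtabright)
res <- run_experiment("sbc", profile = "desk", seed = 1)
print(res)
#> <wta_experiment 'sbc'> profile=desk seed=1
#>   testing reward rate: 0.498
#>   normalized target means:
#>     Sti. 1:   0.3687
#>     Sti. 2:  -0.6264
```

The two stimuli share the identical centered 20×20 gray target
(value 0.5); Sti. 1 has the dark (0.2) background, Sti. 2 the light (0.8)
one. The normalized target means say the network reconstructs the *same*
patch almost a full pooled standard deviation brighter on the dark
background — simultaneous brightness contrast. The testing reward rate is
the fraction of timesteps the unsupervised classifier names the presented
stimulus correctly (chance 0.5 for two stimuli).

```r
cm <- res$cmi[[1]]
sum(abs(cm$cmi) > 0, na.rm = TRUE)   # 29 of 30 neurons context-modulated
max(abs(res$xcorr_diff[[1]]))        # 0.271: pairwise interactions shift too
```

Other experiments: `"distance"`, `"grayscale"`, `"size"` (four stimuli
each: the split-background pair plus two distractor conditions),
`"combined"`, `"anchoring"`. `profile = "paper"` runs the full-scale
protocol (K = 100, 200 learning / 100 testing simulations).

## Command line

```sh
inst/cli/wtabright run  --experiment sbc --profile desk --seed 1 --outdir out/
inst/cli/wtabright generate-stimuli --experiment size --outdir stimuli/
```

Subcommands: `generate-stimuli`, `train`, `test`, `analyze`, `run`
(`--config` takes a JSON file overriding protocol sizes; stimuli are
written as ASCII PGM plus a JSON sidecar describing regions and labels).

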