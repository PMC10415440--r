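# wfsep — water-fat separation and PDFF mapping for CSE-MRI

`wfsep` is an R toolbox for quantitative water-fat separation of
multi-echo chemical-shift-encoded (CSE) gradient-echo MRI, aimed at
readers who want a self-contained, desk-scale implementation of the full
pipeline behind proton density fat fraction (PDFF) mapping: the physics,
a classical fit, learned reconstruction, and the agreement statistics
used to compare methods.

The voxel signal model at echo time $TE_n$ is

$$I_n = e^{-R_2^* TE_n}\, e^{j2\pi \Delta f TE_n}
\left[\rho_W + \rho_F \textstyle\sum_{p=1}^P \alpha_p e^{j2\pi f_{F,p} TE_n}\right],
\qquad \mathrm{PDFF} = \frac{|\rho_F|}{|\rho_W|+|\rho_F|}$$

with water/fat signals $\rho_W,\rho_F$, relaxation $R_2^*$, off-resonance
$\Delta f$, and a six-peak fat spectrum ($\sum_p \alpha_p = 1$). The
package provides:

* **signal model** — `simulate_signal()`, `fat_modulation()`, `pdff()`,
  `default_liver_spectrum()`;
* **synthetic phantoms** — seeded elliptical-compartment abdominal slices
  with smooth off-resonance fields and Rician-magnitude noise
  (`generate_phantom()`, `phantom_dataset()`), plus the preprocessing
  steps `kspace_resize()` (centered k-space cropping) and
  `threshold_mask()`;
* **classical fit** — a voxel-wise VARPRO nonlinear least-squares fit
  with multi-start fieldmap search (`fit_voxel()`, `fit_image()`),
  returning a `wf_fit` object with `print`/`summary`/`coef`/`residuals`
  methods;
* **networks** — a multi-decoder U-Net with self-attention in the
  fieldmap decoder (`build_mdwf_net()`) and a single-decoder U-Net
  comparator (`build_unet()`), built on a small channels-first CNN engine
  included in the package (compiled im2col convolutions, explicit
  backprop, Adam);
* **training** — masked mean-absolute-error training with cosine
  learning-rate decay (`train_network()`, `predict_maps()`);
* **agreement statistics** — `roi_stats()`, `ls_regression()`,
  `bland_altman()`, `anova_posthoc_std()` (Tukey HSD), `mae_map()` and
  `agreement_report()`.

## Worked example

Simulate a 6-echo abdominal slice, fit it voxel-wise, and summarize:

```r
library(wfsep)

sp   <- default_liver_spectrum(1.5)        # six-peak spectrum at 1.5 T
acq  <- acq_params(n_echoes = 6)           # TE1/dTE = 1.29/2.1 ms
maps <- generate_phantom(phantom_config(image_size = 32, seed = 9))
echo <- add_noise(simulate_signal(maps, acq, sp), snr = 50, seed = 1)

fit <- fit_image(echo, sp, mask = maps$mask)
print(fit)
#> VARPRO water-fat fit: 420 voxels, 6 echoes
#>   residual (in-mask): median 0.0265, max 0.0538; 0 voxel(s) flagged

pd <- pdff(fit)
print(pd)
#> PDFF map 32x32: in-mask mean 0.126 (range 0.032 - 0.355)

truth <- pdff(maps)
mean(abs(pd$values[maps$mask] - truth$values[maps$mask]))
#> [1] 0.0096
```

The fitted PDFF tracks the simulated ground truth to well under one
percentage point at this SNR; the residual map and the non-convergence
count are the per-voxel quality controls.

The learned route mirrors the accelerated 3-echo protocol:

```r
acq3  <- acq_params(n_echoes = 3)
train <- phantom_dataset(25, 8, phantom_config(image_size = 64), acq3, sp, seed = 11)
arch  <- build_mdwf_net(network_config(input_size = 64, n_echoes = 3,
                                       encoder_filters = c(8, 16, 32, 64),
                                       bottleneck_filters = 128), seed = 5)
net   <- train_network(arch, train, desk_train_config())
pred  <- predict_maps(net, train[[1]]$echoes)   # maps + PDFF for one slice
```

With the full desk preset (50 subjects, 8 slices each) this training
reaches a held-out in-mask PDFF MAE of about 0.07 in roughly 12 CPU
minutes; the methods vignette discusses what that number does and does
not demonstrate about the architecture at full scale.

A command-line wrapper over the same functions lives in
`inst/cli/wfsep.R` (`simulate`, `fit`, `train`, `eval` subcommands).

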