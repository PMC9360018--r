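# qpiscreen

Multiparametric drug-response screening from quantitative phase imaging
(QPI), for cell biologists and screening labs who measure how cancer cells
respond to therapies by tracking single-cell dry mass over time instead of
running an endpoint viability assay.

A differential phase contrast (DPC) microscope records four images per
location with half-circle illumination (top, bottom, left, right). Opposing
pairs give normalized phase gradients g = (I1 − I2)/(I1 + I2), which are
inverted through the weak-object transfer function H by Tikhonov-regularized
deconvolution,

    phi = F^-1 [ sum_j conj(H_j) F(g_j) / ( sum_j |H_j|^2 + beta ) ],

with beta = 1e-3. Phase integrates to dry mass through the specific
refractive increment alpha = 1.8e-4 m^3/kg:

    m = (lambda / 2 pi) * sum(phi) * A_pixel / alpha.

Cells are segmented (Sobel edges, morphology, optional watershed), masses
linked frame to frame, and each track's specific growth rate is the slope of
an ordinary least-squares fit of mass versus time divided by its intercept
(SGR, h^-1; SGR = ln 2 / t_doubling for proliferating cells). From the
filtered SGR populations the package derives five response parameters per
drug and cell line:

| parameter | definition |
|---|---|
| SGR | per-track growth rate normalized by initial mass (h^-1) |
| EC50 | inflection of the 4-parameter Hill fit SGR(C) = Emax + (E0 − Emax)/(1 + (C/EC50)^HS), with an F-test (p < 0.01) against a flat line deciding response |
| DoR | depth of response (E0 − Emax)/E0; > 1 means cytotoxic (net mass loss) |
| ToR | time of response: first time the Hellinger distance between treated and control SGR distributions exceeds the maximum solvent-vs-untreated control distance, from inverting H(t) = a − b e^{ct} |
| SD at EC50 | standard deviation of single-cell SGR at the tested concentration nearest the EC50 (heterogeneity) |

An in-silico mixing analysis quantifies how small a resistant (control-like)
subpopulation can be detected inside a treated population, scored by the
area under the precision-recall curve normalized against the no-skill
baseline; concordance statistics (Pearson r, Lin's concordance coefficient
with a 10,000-resample bootstrap CI, response confusion matrix) compare the
imaging readout with an endpoint assay.

## Worked example

Synthetic tracks for one drug at six concentrations in triplicate (plus
solvent controls), analysed from the tracks stage:

```r
library(qpiscreen)

layout <- plate_layout(drugs = "doxorubicin",
                       concentrations_uM = c(0.0064, 0.032, 0.16, 0.8, 4, 20))
truth  <- list(E0 = 0.025, Emax = -0.008, EC50_uM = 1.2, HS = 1.3)
tracks <- generate_dose_response_tracks(truth, layout, "doxorubicin",
                                        n_cells_per_location = 10,
                                        sgr_sd = 0.007, noise_cv = 0.02,
                                        seed = 42, locations_per_well = 3)
res <- run_pipeline(tracks, layout, temporal = FALSE)
print(res)
```

```
QPI screening results
  tracks: 720 (accepted=694, low_mass=6, mad_outlier=20)
  doxorubicin: EC50 = 0.908 uM, DoR = 1.21, responded = TRUE
```

720 simulated tracks pass through the filters (6 below the 110 pg debris
threshold, 20 trimmed by the per-condition 3-MAD outlier rule); the fitted
EC50 of 0.91 uM recovers the generating 1.2 uM within the noise of this
small design, the F-test calls a response (p = 7e-4), and DoR = 1.21 > 1
classifies it as cytotoxic (the generating Emax was negative), with a
heterogeneity of SD = 0.0069 h^-1 at the 0.8 uM condition nearest the EC50.
Raw four-frame acquisitions enter the same pipeline through
`reconstruct_phase()`, `segment_cells()`, `measure_cells()` and
`link_tracks()`; a thin command-line front end is included at
`inst/cli/qpi.R`.

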