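# virtualstain

Virtual brightfield staining of multiplex microscopy images in R.

Multiplex modalities — imaging mass cytometry (IMC), cyclic
immunofluorescence, CODEX, multiplex IF — measure dozens of named molecular
marker channels per tissue section, but pathologists, diagnostic workflows
and most pretrained histology models expect transmitted-light brightfield
images of stained tissue (H&E, IHC, special stains). `virtualstain`
synthesizes such images from multiplex data with a deterministic,
physics-based light-absorption model: no generative network, no
hallucinated structure, full user control over colors and intensities. It
is aimed at spatial-biology researchers and imaging scientists who need a
familiar, quantifiable brightfield view of their multiplex panels.

## The model

Each stain is a set of classes *i* (for H&E: nuclei, eosinophilic
stroma/cytoplasm, purple epithelial tissue, erythrocytes). Class *i* has a
transmission color (S<sub>i,R</sub>, S<sub>i,G</sub>, S<sub>i,B</sub>), a
scaling constant k<sub>i</sub>, and an intensity image averaged from its
assigned normalized marker channels:

    I_i = (1/N_i) Σ_m M̃_{i,m}

Per display channel c ∈ {R,G,B}, with background transmission c_c and
detector floor d_c:

    additive:  out_c = c_c − Σ_i k_i I_i (c_c − S_{i,c})            (clipped)
    physical:  out_c = d_c + (c_c − d_c) · exp(−Σ_i k_i I_i (c_c − S_{i,c}))

The physical method is the Beer–Lambert law at three representative
wavelengths: transmitted light decays exponentially with absorber amount,
which reproduces the nonlinear look of real stains and saturates toward
black instead of clipping.

Around this core the package provides: marker-name canonicalization and
lexicon-based channel-to-class assignment (with an LLM route and offline
mock provider, plus a multi-model consensus Jaccard statistic), classical
enhancement filters (median, unsharp, CLAHE on the nuclear intensity,
spline resampling), a seeded degradation simulator for building
image-restoration training pairs (stair-step resolution artifacts, blur,
Gaussian/Poisson/hot-pixel noise in RGB/HSV/HED space), an
enhancement-efficiency index and paired quality metrics (PCC, MSE, MS-SSIM,
PSNR, EMD), OME-TIFF I/O, and a synthetic multiplex fixture generator with
ground truth.

## Worked example

```r
library(virtualstain)

# a seeded IMC-style synthetic image with known ground truth
fx  <- generate_fixture(fixture_spec(size = c(128, 128), pixel_size_um = 1,
                                     n_cells = 40, seed = 7))
img <- normalize_multiplex(fx$image)

# map channels to H&E classes by lexicon
(asn <- assign_by_lexicon(channel_names(img), "h_and_e"))
#> <channel_assignment> stain 'h_and_e'
#>   nuclei           DNA1_Ir191
#>   eosinophilic     Col1A1_Tm169
#>   epithelial       panCK_Eu153
#>   erythrocytes     Ter119_Sm154
#>   unassigned:      CD31_Pt195

# render with the physical (Beer-Lambert) method
he <- render_multiplex(img, stain_preset("h_and_e"), assignment = asn)
#> <rgb_image> 128 x 128 px, pixel 1 x 1 um, range [0.316, 1.000]

# how much does a 3x3 median filter help?
enhancement_efficiency(he, denoise_median(he, 1))
#>   edge_f edge_u noise_f noise_u     E
#> 1  0.183  0.193  0.0190  0.0212  1.06
```

The assignment shows each marker routed to its stain class (`CD31`, an
endothelial marker, has no H&E counterpart and is ignored). The rendered
image spans transmissions from 0.32 (darkest nuclei) to 1.0 (unstained
background). The efficiency index E = 1.06 > 1 means the median filter
removed proportionally more high-frequency noise (−10%) than Sobel edge
signal (−5%) — a favorable trade-off.

A command-line front end over the same functions ships in
`inst/cli/virtualstain.R` with subcommands `convert`, `select-channels`,
`enhance`, `degrade`, `evaluate`, `make-fixture` and `list-presets`, each
supporting `--dry-run`.

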