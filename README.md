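# carotrace

Cooperative minimum-cost-path extraction of carotid artery centerlines
from 3D angiographic volumes, with a synthetic bifurcating-vessel
phantom generator and curve-distance evaluation metrics.

## The problem

Centerlines of the carotid bifurcation — the common carotid artery
(CCA) splitting into the internal (ICA) and external (ECA) branches —
are the usual starting point for vessel registration, segmentation and
geometry analysis in neck MRI. Extracting each centerline as an
independent minimum-cost path is robust globally but fails
characteristically at the bifurcation: when one branch is faintly
imaged, both paths descend the brighter branch and the faint branch's
path only jumps across near its seed, so the two centerlines coincide
where they should diverge.

`carotrace` extracts the two branch paths *cooperatively*. A cost image

&nbsp;&nbsp;&nbsp;&nbsp;*p*(x) = 1 / (ε + *m*(x)<sup>α</sup> *s*(x)<sup>β</sup>),&nbsp;&nbsp;&nbsp;&nbsp;*p̃* = *p* + ω

is built from a multi-scale circular medialness response *m* ∈ [0,1]
and a lumen-intensity similarity *s* ∈ [0,1] estimated from spherical
seed ROIs (ω penalizes path length and so bounds curvature). The
minimal action map *U* solving the Eikonal equation ‖∇*U*‖ = *p̃* is
computed by anisotropic fast marching (first-order upwind scheme,
6-connected front, exact source-ball initialization), and paths are
backtracked from the far seed by RK4 descent of the normalized
gradient at a 0.1 mm step. For the cooperative variants, the branch
path with the lower average cost *U*(end)/length is extracted first; a
constraint region κ — a ρ = 1.75 mm spherical dilation of its
post-bifurcation segment — is assigned a blocking cost *K*, the
neighbor path is re-extracted on the blocked cost, and the first path
is then re-extracted against a region around the corrected neighbor.
The result is a pair of centerlines guaranteed to stay ρ apart beyond
the bifurcation (up to voxelization).

Four extraction variants are provided — independent (`SCIE`),
independent through a shifted bifurcation seed (`SCBIE`), and their
cooperative counterparts (`CCIE`, `CCBIE`) — plus the evaluation stack:
Hausdorff distance, the centerline artery distance
CAD = max(H<sub>ICA</sub>, H<sub>ECA</sub>) with a 3.5 mm failure
threshold, leave-one-out selection of ω, and an exact McNemar test on
paired failure counts.

## Worked example

The package ships a phantom generator, so the full pipeline runs
without any MRI data:

```r
library(carotrace)

# Y-shaped two-sequence phantom whose ECA branch is barely visible
tab <- run_demo(tempfile("demo_"), faint = TRUE)
tab
#>   method     H_ica    H_eca      CAD failed
#> 1   SCIE 0.2095204 7.542345 7.542345   TRUE
#> 2  SCBIE 0.2247321 7.544000 7.544000   TRUE
#> 3   CCIE 0.4745796 2.087253 2.087253  FALSE
#> 4  CCBIE 0.4560330 2.182021 2.182021  FALSE
```

Reading the table: per method, `H_ica`/`H_eca` are the Hausdorff
distances (mm) between the extracted and the ground-truth branch
centerlines, and `CAD` is their maximum. The independent methods put
the ECA centerline ~7.5 mm off (it collapsed onto the bright ICA
branch) and fail the 3.5 mm criterion; the cooperative methods recover
both branches within ~2.2 mm. On the clean equal-contrast phantom
(`faint = FALSE`) all four methods are accurate to well under 1 mm.

The same stages are scriptable step by step:

```r
ph  <- make_phantom(faint_branch_preset())
ci  <- crop_roi(multispectral_cost(list(ph$seq1, ph$seq2),
                                   ph$truth$seeds,
                                   cost_params(omega = 2,
                                               scales = c(1.75, 2.5, 3.5))),
                ph$truth$seeds)
fit <- run_method(ci, ph$truth$seeds, method = "CCBIE")
summary(fit)
plot(fit, truth = ph$truth)
```

or from a shell via the bundled CLI
(`system.file("cli", "carotrace.R", package = "carotrace")`), which
exposes `phantom`, `cost`, `extract`, `evaluate` and `demo`
subcommands operating on NIfTI volumes and JSON seed/centerline files.

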