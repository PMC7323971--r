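# vasc3d

3D reconstruction of colonic-mucosa microvasculature from serial
immunostained sections, and quantification of which microvessels are
visible on magnifying blue-laser imaging (BLI) as a function of their
depth below the mucosal surface.

## The problem

Magnifying narrow-band endoscopy (BLI, ~410 nm) shows superficial
capillaries as brown lines through haemoglobin absorption, but only down
to some depth. To measure that depth one can reconstruct the
microvasculature in 3D from serial sections — a vessel-wall stain (CD34)
that leaves lumens unstained (rings in cross-section) on most slices, an
epithelium stain (CAM5.2) every third slice for the crypt glands — align
and stack the slices, extract the mucosal surface, and measure the depth
from the surface to each vessel's lumen centre. A matched region is then
divided into equal areas; each area gets an endoscopist's visible /
invisible call and a pathologist's nearest-vessel depth, the two depth
distributions are compared with a Mann–Whitney U test

    U = R1 - n1(n1+1)/2,   depth_i = z(lumen centroid_i) - surface(x_i, y_i),

and the visibility boundary is estimated as the midpoint between the
deepest visible and the shallowest invisible vessel.

`vasc3d` implements that pipeline end to end: a synthetic tissue-phantom
generator with exact ground truth (crypt lattice, honeycomb pericryptal
capillary rings or controlled parallel tubes, stain schedule, per-slice
rigid jitter, broken vessel walls, noise), stain segmentation with vessel
lumen filling and broken-wall rescue, rigid slice-to-slice registration
with an anchored sub-pixel refinement, anisotropic volume stacking,
surface extraction, per-component depth measurement, depth-windowed
en-face projections (50/100/150 um), a virtual magnifying-BLI renderer,
and the per-area visibility analysis with an exact/tie-corrected
Mann–Whitney U test. Because the underlying histology of the motivating
study is not deposited, every stage is validated by parameter recovery on
the phantom.

## Worked example

Simulate the default study conditions (100 serial sections of 3 um,
epithelium stain every third slice, honeycomb capillaries around a crypt
lattice), run the whole pipeline, and inspect the analysis:

```r
library(vasc3d)
cfg <- run_config(rng_seed = 3)
res <- run_pipeline(cfg, quiet = TRUE)
print(res$field)
print(res$analysis)
```

```
depth_field (axis mode): 27 components, depths 21.1-239.7 um, 0 voxels excluded
visible:   median 44.9 um (21.1-60.6 um), n = 35
invisible: median 129.6 um (21.1-148.9 um), n = 5
visibility boundary ~ 95.1 um (crossing); 10 censored, 0 corrected, 0 excluded
Mann-Whitney U = 31.5 (n1 = 35, n2 = 5), two-sided p = 0.021 [normal_approx_tie_corrected]
```

27 vessel components were reconstructed between 21 and 240 um below the
surface. Of the 50 analysis areas, 10 had no measurable vessel; areas
where the virtual BLI view (80 um hard cutoff) shows a vessel have a
median nearest-vessel depth of 44.9 um versus 129.6 um where it shows
none — the visible group is significantly shallower, the qualitative
structure of the clinical finding. Setting `output_dir` additionally
writes the series (multi-page TIFF + JSON manifest), transforms CSV,
volume channels, surface map, component-depth CSV, 50/100/150 um
projections, the BLI render, per-area records, a summary JSON and a
manifest with per-file MD5 hashes (a rerun with the same seed reproduces
them bit-for-bit).

A thin command-line front end is installed at `inst/cli/vasc3d`
(`simulate`, `segment`, `register`, `reconstruct`, `project`, `analyze`,
`pipeline`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/vasc3d", package="vasc3d"))')" \
  pipeline --seed 3 --out runs/demo
```

See the vignette (`vignettes/reconstruction-and-visibility.Rmd`) for the
model, parameter and design discussion.

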