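# capcount

Automated counting of white blood cell (WBC) events in nailfold capillary
video.

When a white blood cell's diameter matches that of the capillary it flows
through, it briefly interrupts the red blood column and appears as a bright
moving *visual gap*. Counting these gaps in a capillaroscopy video gives a
non-invasive window on WBC activity — useful for monitoring conditions such
as neutropenia without drawing blood. Doing it by hand is slow and
subjective; `capcount` implements a fully automated pipeline for researchers
working with portable capillaroscope recordings (nominally 30 s of RGB video
at 30 fps, 640 × 480).

## Method

For a video of frames *I₁ … I_T* the pipeline runs:

1. **Frame enhancement** — per-frame, per-channel global histogram
   equalization.
2. **Capillary segmentation** — either the conventional color score
   *Label = ReLU(λ·I_R − (I_G + I_B))²* with λ = 1.5 (capillaries are
   red-dominant), rescaled to 0–255 and thresholded at 80; or a compact
   U-Net encoder–decoder trained with Adam on pixelwise binary
   cross-entropy, thresholded at 150; or a user-supplied manual mask.
3. **Video stabilization** — whole-frame translation registration on the
   capillary *labels* (not the raw frames) by FFT cross-correlation. The
   reference is updated every *p* = 50 frames and a single accumulator keeps
   the history of translations among reference frames, so every frame is
   mapped into the first frame's coordinates and the accumulation composes
   exactly. Frames and masks are shifted alike; the stabilized masks are
   averaged over time and binarized into one robust *ensemble mask*.
4. **Coordinate determination** — per capillary (8-connected component of
   the ensemble mask), the ordered *internal* boundary (the inner edge of
   the hairpin facing the inter-branch gap), an equal number of *external*
   boundary points resampled uniformly in arc length, and the *intermediate*
   pixels on each connecting segment.
5. **Spatiotemporal (ST) map** — element *k* of a frame's capillary vector
   is the mean intensity over coordinate triple *k*; stacking the vectors
   over time gives an n × T map in which each moving gap traces a slanted
   line. The map is median-filtered, row zero-meaned (removing static
   structure), clipped at zero, and Sobel-enhanced.
6. **Event counting** — the Radon transform
   *R(θ, z) = ∫ f(s sinθ + z cosθ, −s cosθ + z sinθ) ds* turns lines into
   polar-map peaks; local maxima are picked, the angle group containing the
   most maxima defines the *base events*, and every other maximum is removed
   if its reconstructed line crosses a base line inside the map. The number
   of surviving lines is the WBC count.

A ground-truthed synthetic video generator (hairpin vessels, moving gaps,
camera-jitter random walk, illumination field, sensor noise) provides the
package's validation surface, since no capillaroscopy recordings are
publicly deposited.

## Worked example

```r
library(capcount)

spec <- synthetic_spec(n_events = 5, jitter_amplitude = 3, seed = 42)
gen  <- generate_video(spec)          # 160 frames, 192 x 256, 30 fps
res  <- wbc_pipeline(gen$video, wbc_config(method = "conventional",
                                           stabilize = TRUE))
print(res)
#> <wbc_result> arm S-Conventional | 160 frames 192x256 @ 30 fps
#>   capillary 1: 5 WBC events
#>   total: 5 events

as.data.frame(res$event_sets[[1]])
#>  event theta   z strength    time_s
#>      1    22 -50 19767.78 0.8524421
#>      2    22 -25 20426.01 1.7512210
#>      3    22  -3 19902.61 2.5421465
#>      4    22  26 20056.72 3.5847301
#>      5    22  50 19870.11 4.4475579
```

The five detected lines match the five injected gaps: `theta` is the line's
normal angle from the time axis (all events share the flow-speed-determined
slope, hence near-identical angles), `z` its offset from the ST-map center,
and `time_s` the moment the gap passes the midpoint of the capillary path.
`plot(res)` draws the processed ST map with the reconstructed lines;
`run_pipeline(frame_dir, config, out_dir = "out")` writes a JSON/CSV/PNG
report bundle. A thin command-line wrapper lives at `inst/cli/capcount.R`
(subcommands `run`, `synth`, `train`).

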