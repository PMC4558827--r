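# elewatch

Automatic detection of free-ranging elephants for early-warning
monitoring, in two complementary modalities:

* **Acoustic** — elephants produce powerful low-frequency rumbles
  (fundamental frequency roughly 10–30 Hz, harmonic stacks shaped by
  vocal-tract resonances) that carry for kilometers, so they can be
  detected out of sight. The pipeline is: magnitude spectrogram (300 ms
  frames, 2/3 overlap) → image-processing enhancement that boosts
  well-localized spectro-temporal ridges and attenuates diffuse wind and
  rain energy → Greenwood-frequency cepstral coefficients (GFCC — a
  cepstrum on the Greenwood cochlear warp f(x) = A·(10^{a·x} − k)
  fitted to the animal's hearing range) → context windows of
  mean‖variance statistics → linear SVM → interval-level event
  decisions scored against label-track annotations.
* **Visual** — in sight, elephants' large gray-brown, weakly textured
  bodies are found by color rather than shape: a linear skin-color
  model in CIELAB → mean-shift over-segmentation of each frame →
  segment scoring → temporal linking and merging of candidate segments
  into tracks → refinement that keeps detections trackable at a similar
  location over many frames → per-pixel-mask evaluation by object-frame.

Because the underlying field recordings are not publicly deposited, the
package ships seeded synthetic generators for both modalities: annotated
soundscapes (rumbles at calibrated in-band SNR over wind, rain and
engine confounds) and annotated frame sequences (elephant blobs at near
and far scales under vegetation occlusion, shadows, camera jitter and
illumination drift). Both pipelines are evaluated end-to-end on these
benchmarks with detection rate and false-positive rate (the fraction of
emitted detections that match no ground truth).

## Worked example

```r
library(elewatch)

# a 30 s soundscape: one rumble over wind at 0 dB in-band SNR
spec <- soundscape_spec(
  30, 4000,
  events = list(list(spec = rumble_spec(duration = 3), onset = 12)),
  noises = list(list(spec = noise_spec("wind", 30), onset = 0)),
  in_band_snr = 0, seed = 7)
scene <- compose_soundscape(spec)
scene$events
#>   start end  label
#> 1    12  15 rumble

# enhancement raises the ridge-to-background ratio of the call
sg  <- stft_spectrogram(scene$clip)
enh <- enhance_spectrogram(sg)
round(c(before = snr_ridge(sg,  scene$events[1, ], c(5, 150)),
        after  = snr_ridge(enh, scene$events[1, ], c(5, 150))), 2)
#> before  after
#>   1.75   9.27
```

The before/after numbers are the mean in-band energy inside the
annotated call interval over the mean outside it, in dB: the call
stands 1.8 dB above background in the raw spectrogram and 9.3 dB after
enhancement. The full benchmarks are one call each:

```r
pair <- run_acoustic_benchmark_pair(1)   # ~1 min
pair$enhanced$report
#> <eval_report: 19/21 truths detected (90.5%), FPR 13.6% of 22 detections>
pair$plain$report
#> <eval_report: 17/21 truths detected (81.0%), FPR 19.0% of 21 detections>

vis <- run_visual_benchmark(1)           # ~10 min
vis$near
#> <eval_report: 1500/1500 truths detected (100.0%), FPR 0.0% of 1100 detections>
```

Disabling enhancement costs recall and raises the false-positive rate —
the core claim of the acoustic method. A command-line surface wrapping
the same functions is installed at `exec/elewatch`
(`simulate-audio`, `enhance`, `train-acoustic`, `detect-acoustic`,
`eval-acoustic`, `simulate-scenes`, `train-visual`, `detect-visual`,
`eval-visual`, `summarize`).

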