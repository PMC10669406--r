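# aimorse

Camera-based Morse code entry is one of the few text-input channels left
to people with severe motor impairments: mouth openings become dots and
dashes, mouth closings separate elements and characters, and a decoder
turns the element stream into text. What makes this hard in practice is
that "short" and "long" are user- and session-specific and drift as the
user tires. `aimorse` implements an adaptive fuzzy time-recognition
controller that tracks the dot/dash duration threshold on-line, plus the
supporting pieces of the pipeline: mouth-state extraction from 68-point
facial landmark streams, illumination compensation and automatic image
straightening for the landmark detector, a ground-truth-labeled typist
simulator, and a command-line interface.

## The controller in brief

For each duration $I(k)$ (ms), with threshold carried over from the
previous step:

* classify: long iff $I(k) \ge \mathrm{threshold}_{k-1}$;
* limit: $x(k) = I(k)$ below the threshold, $I(k)/3$ at or above it
  (folding dashes onto the dot scale);
* error: $e_k = \mathrm{clamp}\big((x(k) - Y(k-1))/L,\,-1,\,1\big)$ with
  tolerance $L = 100$ ms;
* fuzzy correction: $e'_k$ = center-of-gravity defuzzification of $e_k$
  over five triangular sets (LN, SN, ZE, SP, LP) on $[-1, 1]$;
* update: $Y(k) = Y(k-1) + e'_k L$, $\ \mathrm{threshold}_k = 2\,Y(k)$.

Two independent trackers run per stream — one for openings
(dot/dash), one for closings (short silence continues a character, long
silence emits it).

## Worked example

Simulate a motor-impaired typist (15% duration jitter, 1.5× slow-down
across the stream) typing "hello world", then decode it blind:

```r
library(aimorse)

truth <- generate_timing_stream("hello world", preset_profile("disabled", seed = 11))
head(truth$events, 4)
#>    state start_ms duration_ms
#> 1   OPEN   0.0000    183.0323
#> 2 CLOSED 183.0323    202.3931
#> 3   OPEN 385.4254    161.8359
#> 4 CLOSED 547.2613    166.9092

res <- decode_stream(truth$events)
res$text
#> [1] "hellowosld"

recognition_rate(res, truth)
#> element recognition rate: 96.88% (62/64 elements)
#> character accuracy:       90.00%
```

The decoder never saw the true dot length: it estimated the threshold
from the first few events and tracked it from there. Of 64 timed events
it misread two — a dash compressed far enough to read as a dot, turning
the "r" of "world" into "s" (spaces are not encoded, so the reference
text is `helloworld`). The threshold trajectory is in
`res$trace`; at this noise level an occasional error is expected, and
the expert preset (5% jitter, no drift) decodes the same text
perfectly.

The CLI wraps the same functions:

```sh
Rscript inst/cli/aimorse.R simulate --text sos --profile expert --seed 3 --out stream.csv
Rscript inst/cli/aimorse.R decode --in stream.csv
#> sos
```

Subcommands: `decode`, `simulate`, `evaluate`, `segment` (landmark CSV →
interval CSV), `compensate` and `straighten`.

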