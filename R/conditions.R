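## Structured error conditions. Every error raised by the package carries the
## superclass "limbAlignError" plus a specific class so callers (and tests) can
## discriminate failure modes without parsing messages.

.laStop <- function(class, message, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "limbAlignError", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

## Landmark procedures fail per anatomic region; the region travels with the
## condition so extractLandmarks() can aggregate.
.landmarkFailure <- function(region, message, parent = NULL) {
  .laStop("limbAlign_landmark_failure",
          sprintf("landmark-failure(%s): %s", region, message),
          region = region, parent = parent)
}

.isLandmarkFailure <- function(e) inherits(e, "limbAlign_landmark_failure")
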