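# Desk-scale phantom and matching segmentation parameters used across the
# unit tests (160 px section; the acceptance tests use the full 512 px
# defaults).

smallSpec <- function(...) {
  args <- list(...)
  defaults <- list(imageSize = 160, fruitRadius = 66, peelThickness = 7,
                   cavityRadius = 20, nSegments = 7, septumWidth = 2,
                   noiseSd = 0, seed = 1)
  do.call(PhantomSpec, utils::modifyList(defaults, args))
}

smallParams <- function(...) {
  args <- list(...)
  defaults <- list(erosionCoreRadius = c(cross = 6, longitudinal = 9))
  do.call(SegmentationParams, utils::modifyList(defaults, args))
}
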