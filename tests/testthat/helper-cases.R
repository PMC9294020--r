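# Solved reference cases are reused across many tests; cache them.
.case_cache <- new.env(parent = emptyenv())
case_fit <- function(k) {
  key <- as.character(k)
  if (is.null(.case_cache[[key]])) .case_cache[[key]] <- stent_flow(k)
  .case_cache[[key]]
}

# Case-1 geometry with the side holes removed (unporous, hole-less stent).
no_hole_unporous_scenario <- function() {
  sc <- make_scenario(1)
  sc$stent$n_side_holes <- 0L
  sc$stent$holes_per_coil <- 0L
  sc$side_holes_enabled <- FALSE
  sc$case_id <- NA_integer_
  validate_scenario(sc)
}
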