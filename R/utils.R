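# Run code with a private RNG stream, leaving the caller's stream untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Values in the mask with a valid ADC estimate, as a plain vector.
masked_adc_values <- function(adc, mask) {
  assert_same_grid(adc$grid, mask$grid, "ADC map and mask")
  sel <- mask$mask & adc$valid
  adc$values[sel]
}
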