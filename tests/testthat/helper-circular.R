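# circular mean of angles in radians
circ_mean <- function(phi) {
  atan2(mean(sin(phi)), mean(cos(phi)))
}

# signed circular difference a - b wrapped to (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  if (d > pi) d - 2 * pi else d
}
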