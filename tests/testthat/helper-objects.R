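# Shared builders for tests. Small, deterministic objects.

ref_human <- function(vd_correction = 0.01) {
  make_subject("human", sex = "male", age_years = 40, body_weight_kg = 73,
               height_cm = 176, vd_correction = vd_correction)
}

ref_rat <- function(vd_correction = 0.05, weight_kg = 0.25) {
  make_subject("rat", body_weight_kg = weight_kg,
               vd_correction = vd_correction)
}

# brute-force 1-um slab oracle for needle volume / lateral area between two
# tip distances (independent of the closed forms under test)
slab_needle <- function(s_lo, s_hi, design, ds = 1) {
  if (s_hi <= s_lo) return(c(V = 0, SA = 0))
  grid <- seq(s_lo, s_hi, by = ds)
  if (grid[length(grid)] < s_hi) grid <- c(grid, s_hi)
  mids <- (utils::head(grid, -1) + utils::tail(grid, -1)) / 2
  dss <- diff(grid)
  h <- design$needle_height_um
  w <- design$needle_width_um * mids / h
  l <- design$needle_length_um * mids / h
  # slant correction per face pair: faces normal to width / to length
  sw <- sqrt(1 + (design$needle_width_um / (2 * h))^2)
  sl <- sqrt(1 + (design$needle_length_um / (2 * h))^2)
  c(V = sum(w * l * dss),
    SA = sum((2 * w * sl + 2 * l * sw) * dss))
}
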