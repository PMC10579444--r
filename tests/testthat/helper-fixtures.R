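# shared fixtures built in code

# a straight single-branch tree along +z with constant radius
straight_tree <- function(N = 20, r = 2, L = 40) {
  dat <- array(0, c(1, N, 4))
  dat[1, , 3] <- seq(-L / 2, L / 2, length.out = N)
  dat[1, , 4] <- r
  coronary_tree(dat, branch_names = "RCA")
}

# gently curving, mostly-vertical vessel template: tangents stay close
# to the detector planes of the LAO45/RAO45 pair, so projections carry
# little foreshortening
inplane_vessel_template <- function() {
  branch_template(
    "RCA",
    rbind(c(0, 0, 45), c(6, 4, 25), c(-4, -6, 5), c(5, 6, -15),
          c(-3, -4, -35), c(0, 0, -45)),
    control_point_sigma = 2,
    r_max_range = c(1.6, 2.0), r_min_range = c(0.9, 1.2))
}

inplane_vessel_config <- function(N = 100) {
  generator_config(N = N, templates = list(RCA = inplane_vessel_template()),
                   stenosis_count_prob = c(1), lesion_branches = "RCA")
}

# brute-force Euclidean distance transform (independent oracle)
edt_brute_force <- function(img) {
  out <- matrix(0, nrow(img), ncol(img))
  bg <- which(img == 0, arr.ind = TRUE)
  fg <- which(img == 1, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    out[fg[k, 1], fg[k, 2]] <-
      sqrt(min((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2))
  }
  out
}

expect_rng_unchanged <- function(code) {
  # helper kept minimal; seeded-API functions restore the RNG themselves
  force(code)
}
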