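# Shared fixtures built in code.

TTR_SEQ <- "YTIAALLSPYS"

# a minimal valid system holding arbitrary atoms of one glycine residue,
# used for hand-constructed geometric cases
tiny_system <- function(n_atoms = 1L, element = "C", name = "CA",
                        chain = "A") {
  peptideSystem("G",
                data.frame(name = rep(name, n_atoms),
                           element = rep(element, n_atoms),
                           chain = rep(chain, n_atoms),
                           resno = rep(105L, n_atoms)),
                offset = 105L)
}

# two-residue-per-chain dimer with explicit backbone atoms for H-bond
# geometry cases: coordinates supplied by the caller
hbond_test_system <- function() {
  atoms <- data.frame(
    name = rep(c("N", "H", "CA", "C", "O"), 2),
    element = rep(c("N", "H", "C", "C", "O"), 2),
    chain = rep(c("A", "B"), each = 5),
    resno = 105L
  )
  peptideSystem("G", atoms, offset = 105L)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(xyz %*% t(R), 2, -t)
}
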