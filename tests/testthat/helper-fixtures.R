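# Shared fixtures, built once per test run. Everything is generated in code;
# no binary data ships with the package.

helix20 <- make_ideal_polypeptide(20)
helix20_map <- synthesize_map(helix20)

# independent brute-force dihedral (explicit atan2 vector formula, written
# separately from the package's implementation)
brute_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cx <- function(a, b) c(a[2]*b[3]-a[3]*b[2], a[3]*b[1]-a[1]*b[3],
                         a[1]*b[2]-a[2]*b[1])
  n1 <- cx(b1, b2); n2 <- cx(b2, b3)
  m1 <- cx(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

expect_rms_close <- function(a, b, tol) {
  expect_lt(sqrt(mean((a - b)^2)) / max(sqrt(mean(b^2)), 1e-12), tol)
}

vnorm_test <- function(v) sqrt(sum(v^2))
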