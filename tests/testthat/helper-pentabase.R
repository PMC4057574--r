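# Shared fixtures and expectation helpers.

# The running example sequence: dense form and its E-inserted variant.
eq2a <- function() seqvec("CTGATAAC")
eq2b <- function() seqvec("C1 T2 E3 G4 A5 T6 E7 E8 A9 A10 C11")

expect_seq_equal <- function(a, b, ...) {
  expect_true(seq_equal(a, b, ...),
              info = paste("expected:", seq_text(b, "explicit"),
                           "got:", seq_text(a, "explicit")))
}

expect_opvec_equal <- function(a, b) {
  expect_identical(a$place, b$place)
  expect_identical(a$exponent, b$exponent)
}

# Independent brute-force oracle for group composition: step the generator
# one move at a time around the five-letter cycle, never using mod arithmetic.
step_cycle <- c("E" = "C", "C" = "A", "A" = "T", "T" = "G", "G" = "E")
oracle_shift <- function(base, times) {
  for (i in seq_len(times)) base <- step_cycle[[base]]
  base
}

random_opvec <- function(n = 20L, p_identity = 0.3) {
  k <- sample(0:4, n, replace = TRUE)
  k[stats::runif(n) < p_identity] <- 0L
  opvec(seq_len(n), k)
}
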