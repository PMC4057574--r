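test_that("parsing handles plain letters, tokens and the empty identity", {
  s <- eq2a()
  expect_equal(seq_places(s), 1:8)
  expect_equal(unname(seq_letters(s)), strsplit("CTGATAAC", "")[[1]])
  expect_equal(s$alphabet, "DNA")

  tok <- seqvec("C1 T2 E3 G4")
  expect_equal(seq_places(tok), 1:4)
  expect_equal(unname(seq_letters(tok))[3], "E")

  d0 <- seqvec("")
  expect_equal(length(seq_places(d0)), 0L)
  expect_equal(n_bases(d0), 0L)

  # normalisation and round trips
  expect_seq_equal(seqvec("c t g a"), seqvec("CTGA"))
  expect_seq_equal(seqvec(seq_text(tok, "explicit")), tok)
  expect_equal(seqvec("AUCG")$alphabet, "RNA")

  expect_error(seqvec("CXG"), "not in the DNA alphabet")
  expect_error(seqvec("C1 T1"), "duplicate place")
  expect_error(seqvec("C0 T1"), "positive")
})

test_that("the real-base count ignores every E, explicit or implicit", {
  expect_equal(n_bases(eq2a()), 8L)
  expect_equal(n_bases(eq2b()), 8L)
  expect_equal(n_bases(seqvec("")), 0L)
})

test_that("E insertion shifts place numbers upward by the block size", {
  s <- insert_E(seqvec("ACGT"), 1, 1)
  expect_equal(seq_text(s, "explicit"), "A1 E2 C3 G4 T5 |E...")
  s <- insert_E(s, 4, 2)
  expect_equal(seq_text(s, "explicit"), "A1 E2 C3 G4 E5 E6 T7 |E...")
  expect_equal(unname(seq_letters(s)), c("A", "E", "C", "G", "E", "E", "T"))
  expect_equal(seq_places(s), 1:7)

  # ACCGT -> ACC(E)GT -> set place 4 to A via the group action -> ACCAGT
  t2 <- insert_E(seqvec("ACCGT"), 3, 1)
  t2 <- op_apply(t2, opvec(4, "u"))
  expect_equal(seq_text(t2, "conventional"), "ACCAGT")

  expect_error(insert_E(seqvec("ACGT"), 2, 0), "positive")
  expect_error(insert_E(seqvec("ACGT"), -1, 1), "non-negative")
})

test_that("E deletion requires explicit E's and renumbers downward", {
  s <- seqvec("A1 C2 C3 E4 E5 G6 T7")
  expect_equal(seq_text(delete_E(s, c(4, 5)), "explicit"),
               "A1 C2 C3 G4 T5 |E...")
  expect_seq_equal(delete_E(s, integer()), s)
  expect_error(delete_E(s, 2), "do not hold an explicit E")
  expect_error(delete_E(s, 9), "not explicit entries")
  # insertion then deletion of the same block is the identity
  expect_seq_equal(delete_E(insert_E(eq2a(), 3, 2), c(4, 5)), eq2a())
})

test_that("brace and angle operators implement the two E-erasure notations", {
  b <- braces(eq2b())
  expect_equal(seq_places(b), c(1L, 2L, 4L, 5L, 6L, 9L, 10L, 11L))
  expect_seq_equal(braces(b), b)  # idempotent

  a <- angle(eq2b())
  expect_equal(seq_places(a), 1:8)
  expect_equal(seq_text(a, "conventional"), "CTGATAAC")
  expect_seq_equal(angle(braces(eq2b())), a)
  expect_seq_equal(angle(seqvec("E1 E2")), seqvec(""))

  # iterated form, including interleaved indels: delete G3 and A7 from the
  # normalised vector, then renormalise
  dj1 <- op_apply(a, opvec(c(3, 7), c("r", "d")))  # G->E, A->E
  expect_equal(seq_text(angle(dj1), "explicit"),
               "C1 T2 A3 T4 A5 C6 |E...")
  expect_seq_equal(angle_t(dj1, 2), angle(angle(dj1)))
  expect_seq_equal(angle_t(dj1, 0), dj1)
  expect_seq_equal(angle_t(dj1, 1), angle(dj1))
  expect_error(angle_t(dj1, -1), "non-negative")
})

test_that("reversal flips base order and the direction label", {
  s <- seqvec("CGACTAT")
  r <- seq_reverse(s)
  expect_equal(seq_text(r, "conventional"), "TATCAGC")
  expect_equal(r$direction, "3to5")
  expect_seq_equal(seq_reverse(r), s)
  one <- seqvec("A")
  expect_equal(seq_text(seq_reverse(one), "conventional"), "A")
  expect_equal(seq_reverse(one)$direction, "3to5")
})

test_that("text rendering distinguishes conventional and explicit modes", {
  s <- seqvec("A1 C2 G3 E4 T5")
  expect_equal(seq_text(s, "conventional"), "ACGT")
  expect_equal(seq_text(s, "explicit"), "A1 C2 G3 E4 T5 |E...")
  expect_equal(seq_text(seqvec(""), "conventional"), "")
  expect_equal(as.character(s), "ACGT")
})

test_that("random sequences are seed-deterministic with the right E rate", {
  a <- random_seqvec(50, 0.2, seed = 42)
  b <- random_seqvec(50, 0.2, seed = 42)
  expect_seq_equal(a, b)
  expect_equal(length(seq_places(random_seqvec(0, 0.5, seed = 1))), 0L)
  big <- random_seqvec(1000, 0.2, seed = 7)
  frac <- sum(big$index == 0L) / 1000
  expect_true(abs(frac - 0.2) < 0.05)
})

test_that("bookkeeping operations never change the conventional sequence", {
  for (seed in 1:25) {
    s <- random_seqvec(sample(0:25, 1), p_explicit_E = 0.25, seed = seed)
    conv <- seq_text(s, "conventional")
    n <- n_bases(s)
    after <- sample(0:5, 1)
    ins <- insert_E(s, after, sample(1:3, 1))
    expect_equal(seq_text(ins, "conventional"), conv)
    expect_equal(n_bases(ins), n)
    for (op in list(braces, angle, seq_reverse)) {
      expect_equal(n_bases(op(s)), n)
    }
    expect_equal(seq_text(braces(s), "conventional"), conv)
    expect_equal(seq_text(angle(s), "conventional"), conv)
  }
})

test_that("direction-sensitive and -insensitive comparison are available", {
  a <- seqvec("ACGT")
  b <- seqvec("ACGT", direction = "3to5")
  expect_false(seq_equal(a, b))
  expect_true(seq_equal(a, b, ignore_direction = TRUE))
  expect_false(seq_equal(a, seqvec("ACGU")))  # same indices, other alphabet
  # explicit vs implicit E status
  expect_false(seq_equal(seqvec("A1 E2 C3"), seqvec("A1 C3")))
  expect_true(seq_equal(seqvec("A1 E2 C3"), seqvec("A1 C3"),
                        ignore_explicit_E = TRUE))
})
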