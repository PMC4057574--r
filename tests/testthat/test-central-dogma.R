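test_that("edit scripts reproduce the substitution-plus-insertion example", {
  # CGT -> GTA on places 1-3, then insert GC after the 3rd base
  dj <- seqvec("CGTAT")
  script <- edit_script(
    edit_insertE(3, 2),
    edit_substitute(opvec(1:5, c("d", "l", "l", "l", "r")))
  )
  dk <- apply_edit_script(dj, script)
  expect_equal(seq_text(dk, "explicit"), "G1 T2 A3 G4 C5 A6 T7 |E...")

  # the same transformation phrased substitution-first
  alt <- edit_script(
    edit_substitute(opvec(1:3, c("d", "l", "l"))),
    edit_insertE(3, 2),
    edit_substitute(opvec(4:5, c("l", "r")))
  )
  expect_seq_equal(apply_edit_script(dj, alt), dk)

  expect_seq_equal(apply_edit_script(dj, edit_script()), dj)

  tr <- apply_edit_script(dj, script, trace = TRUE)
  expect_length(tr, 3L)
  expect_seq_equal(tr[[1]], dj)
  expect_seq_equal(tr[[3]], dk)
})

test_that("an edit script composed with its inverse is the identity", {
  for (seed in 1:15) {
    s <- random_seqvec(12, 0.2, seed = seed)
    script <- withr::with_seed(seed + 500, {
      # a substitution, an insertion into the new frame, another substitution
      edit_script(
        edit_substitute(random_opvec(10)),
        edit_insertE(sample(0:8, 1), sample(1:3, 1)),
        edit_substitute(random_opvec(12))
      )
    })
    out <- apply_edit_script(s, script)
    back <- apply_edit_script(out, edit_inverse(script))
    expect_seq_equal(back, s)
  }
  # deletion steps invert to the insertions restoring the deleted places
  s <- seqvec("A1 C2 C3 E4 E5 G6 T7")
  script <- edit_script(edit_deleteE(c(4, 5)))
  expect_seq_equal(apply_edit_script(apply_edit_script(s, script),
                                     edit_inverse(script)), s)
})

test_that("recombination swaps segments via paired E-padding operators", {
  r <- recombine(seqvec("GETAGT"), c(3, 6), seqvec("ATAGCTA"), c(3, 7))
  expect_equal(seq_text(r$padded_c, "explicit"),
               "G1 E2 E3 E4 E5 E6 E7 T8 A9 G10 T11 |E...")
  expect_equal(seq_text(r$padded_d, "explicit"),
               "A1 T2 A3 G4 C5 T6 A7 E8 E9 E10 E11 |E...")
  expect_equal(op_tokens(r$op_c, n = 11),
               c("n", "n", "u", "l", "r", "d", "u", "u", "d", "r", "u"))
  expect_equal(op_tokens(r$op_d, n = 11),
               c("n", "n", "d", "r", "l", "u", "d", "d", "u", "l", "d"))
  expect_equal(seq_text(r$out_c, "explicit"),
               "G1 E2 A3 G4 C5 T6 A7 E8 E9 E10 E11 |E...")
  expect_equal(seq_text(r$out_d, "explicit"),
               "A1 T2 E3 E4 E5 E6 E7 T8 A9 G10 T11 |E...")
  expect_opvec_equal(op_inverse(r$op_c), r$op_d)

  expect_error(recombine(seqvec("GETAGT"), c(4, 3), seqvec("ATAGCTA"), c(3, 7)),
               "zero-length")
  expect_error(recombine(seqvec("GETAGT"), c(3, 9), seqvec("ATAGCTA"), c(3, 7)),
               "explicit span")
  expect_error(recombine(seqvec("ACGT"), c(1, 2), seqvec("AUCG"), c(1, 2)),
               "alphabet mismatch")
})

test_that("recombination conserves base content and inverts when aligned", {
  for (seed in 1:25) {
    sc <- random_seqvec(12, 0, seed = seed)
    sd <- random_seqvec(12, 0, seed = seed + 300)
    segs <- withr::with_seed(seed + 600, {
      start <- sample(1:6, 1)
      list(c(start, start + sample(0:4, 1)), c(start, start + sample(0:4, 1)))
    })
    r <- recombine(sc, segs[[1]], sd, segs[[2]])
    # multiset of real bases is conserved across the pair
    pool_in <- sort(c(unname(seq_letters(braces(sc))),
                      unname(seq_letters(braces(sd)))))
    pool_out <- sort(c(unname(seq_letters(braces(r$out_c))),
                       unname(seq_letters(braces(r$out_d)))))
    expect_equal(pool_out, pool_in)
    # segments starting at the same place give mutually inverse operators
    expect_opvec_equal(op_inverse(r$op_c), r$op_d)
    # swapping a segment with identical content changes nothing conventional
    same <- recombine(sc, segs[[1]], sc, segs[[1]])
    expect_equal(seq_text(same$out_c, "conventional"),
                 seq_text(sc, "conventional"))
  }
})

test_that("transcription relabels the alphabet without touching indices", {
  s <- complement_seq(seqvec("TCATEAGCTGA"))
  r <- transcribe(s)
  expect_equal(r$alphabet, "RNA")
  expect_equal(unname(seq_letters(r)), strsplit("AGUAEUCGACU", "")[[1]])
  expect_identical(r$place, s$place)
  expect_identical(r$index, s$index)
  expect_equal(n_bases(r), n_bases(s))
  expect_equal(transcribe(seqvec("E1 E2"))$alphabet, "RNA")
  expect_error(transcribe(seqvec("AUCG")), "DNA")
})

test_that("splicing substitutes introns by explicit E's in place", {
  pre <- seqvec("A1 G2 U3 A4 E5 U6 C7 G8 A9 C10 U11")
  spl <- splice(pre, list(c(2, 4)))
  expect_equal(seq_text(spl, "explicit"),
               "A1 E2 E3 E4 E5 U6 C7 G8 A9 C10 U11 |E...")
  expect_identical(spl$place, pre$place)  # no renumbering
  expect_seq_equal(splice(pre, list()), pre)
  expect_error(splice(pre, list(c(2, 4), c(4, 6))), "overlap")
  expect_error(splice(pre, list(c(10, 14))), "outside")
  expect_error(splice(seqvec("ACGT"), list(c(1, 2))), "RNA")
  # splice then angle equals angle of the manual E-substitution
  manual <- op_apply(pre, op_diff(pre, splice(pre, list(c(2, 4)))))
  expect_seq_equal(angle(spl), angle(manual))
})

test_that("maturation is the angle normalisation of the transcript", {
  spl <- seqvec("A1 E2 E3 E4 E5 U6 C7 G8 A9 C10 U11")
  m <- mature(spl)
  expect_equal(seq_text(m, "explicit"), "A1 U2 C3 G4 A5 C6 U7 |E...")
  expect_seq_equal(mature(m), m)
  expect_equal(n_bases(mature(seqvec("E1 E2", alphabet = "RNA"))), 0L)
})

test_that("the central-dogma chain turns sense DNA into mature mRNA", {
  cd <- central_dogma(seqvec("TCATEAGCTGA"), introns = list(c(2, 4)))
  expect_equal(unname(seq_letters(cd$antisense)),
               strsplit("AGTAETCGACT", "")[[1]])
  expect_equal(unname(seq_letters(cd$pre_mrna)),
               strsplit("AGUAEUCGACU", "")[[1]])
  expect_equal(seq_text(cd$mature, "conventional"), "AUCGACU")
  out <- seq_text(cd$mature, "conventional")
  expect_false(grepl("[TE]", out))

  # without introns the mature mRNA is the complement transcript
  plain <- central_dogma(seqvec("TCATEAGCTGA"))
  expect_equal(seq_text(plain$mature, "conventional"),
               seq_text(transcribe(complement_seq(seqvec("TCATEAGCTGA"))),
                        "conventional"))
  # sense-strand option
  sense <- central_dogma(seqvec("ACGT"), complement = FALSE)
  expect_equal(seq_text(sense$mature, "conventional"), "ACGU")
  # degenerate all-E input
  empty <- central_dogma(seqvec("E1 E2"))
  expect_equal(n_bases(empty$mature), 0L)
})

test_that("codon partition groups letters by reading frame", {
  m <- seqvec("AUCGACU")
  expect_equal(codon_partition(m, 0), c("AUC", "GAC", "U"))
  expect_equal(codon_partition(m, 1), c("A", "UCG", "ACU"))
  expect_equal(codon_partition(m, 2), c("AU", "CGA", "CU"))
  expect_equal(codon_partition(seqvec("", alphabet = "RNA")), character())
  expect_error(codon_partition(seqvec("A1 E2 C3", alphabet = "RNA")),
               "not matured")
  expect_error(codon_partition(m, 3), "frame")
})
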