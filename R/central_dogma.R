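# Higher-level procedures on sequence vectors: ordered edit scripts,
# recombination between two sequences, and the central-dogma chain
# complement -> transcription -> splicing -> maturation -> codon partition.

#' Edit-script steps
#'
#' An edit script is an ordered list of steps applied left-to-right:
#' E insertions, E deletions, and substitutions by an operator vector
#' (which never change place numbering).
#'
#' @param after_place,count As in [insert_E()].
#' @param places As in [delete_E()].
#' @param op An [opvec()].
#' @return A single edit step (for `edit_*`) or an `edit_script` object.
#' @seealso [apply_edit_script()], [edit_inverse()]
#' @name edit_script
NULL

#' @rdname edit_script
#' @param ... Edit steps built with `edit_insertE()`, `edit_deleteE()`,
#'   `edit_substitute()`.
#' @export
edit_script <- function(...) {
  steps <- list(...)
  ok <- vapply(steps, function(x) inherits(x, "edit_step"), TRUE)
  if (!all(ok)) stop("all arguments must be edit steps")
  structure(steps, class = "edit_script")
}

#' @rdname edit_script
#' @export
edit_insertE <- function(after_place, count = 1L) {
  structure(list(type = "insertE", after_place = as.integer(after_place),
                 count = as.integer(count)), class = "edit_step")
}

#' @rdname edit_script
#' @export
edit_deleteE <- function(places) {
  structure(list(type = "deleteE", places = as.integer(places)),
            class = "edit_step")
}

#' @rdname edit_script
#' @export
edit_substitute <- function(op) {
  stopifnot(inherits(op, "opvec"))
  structure(list(type = "substitute", op = op), class = "edit_step")
}

#' @export
print.edit_script <- function(x, ...) {
  cat(sprintf("<edit_script  %d step(s)>\n", length(x)))
  for (st in x) {
    cat(" ", switch(st$type,
      insertE = sprintf("insertE after %d x%d", st$after_place, st$count),
      deleteE = sprintf("deleteE {%s}", paste(st$places, collapse = ",")),
      substitute = sprintf("substitute %s",
                           paste0(z5_alias(z5(st$op$exponent)), st$op$place,
                                  collapse = " "))
    ), "\n")
  }
  invisible(x)
}

#' Apply an edit script to a sequence
#'
#' Steps are applied in order; substitutions act through [op_apply()] and
#' therefore never renumber, while E insertions/deletions shift place numbers
#' as usual.
#'
#' @param s A `seqvec`.
#' @param script An [edit_script()].
#' @param trace If `TRUE`, return the list of intermediate states instead of
#'   just the final vector (element 1 is the input, element `k + 1` the state
#'   after step `k`).
#' @return A `seqvec`, or a list of `seqvec`s when `trace = TRUE`.
#' @export
apply_edit_script <- function(s, script, trace = FALSE) {
  stopifnot(inherits(s, "seqvec"), inherits(script, "edit_script"))
  states <- vector("list", length(script) + 1L)
  states[[1L]] <- s
  for (k in seq_along(script)) {
    st <- script[[k]]
    s <- switch(st$type,
      insertE = insert_E(s, st$after_place, st$count),
      deleteE = delete_E(s, st$places),
      substitute = op_apply(s, st$op),
      stop("unknown edit step type: ", st$type)
    )
    states[[k + 1L]] <- s
  }
  if (trace) states else s
}

#' Invert an edit script
#'
#' Reverses the step order, inverting each step: substitutions invert
#' componentwise, an E insertion becomes the deletion of the inserted block,
#' and an E deletion becomes the insertions restoring the deleted places.
#' Applying a script and then its inverse is the identity.
#'
#' @param script An [edit_script()].
#' @return An `edit_script`.
#' @export
edit_inverse <- function(script) {
  stopifnot(inherits(script, "edit_script"))
  inv <- list()
  for (st in rev(script)) {
    inv <- c(inv, switch(st$type,
      insertE = list(edit_deleteE(st$after_place + seq_len(st$count))),
      deleteE = lapply(sort(st$places), function(p) edit_insertE(p - 1L, 1L)),
      substitute = list(edit_substitute(op_inverse(st$op)))
    ))
  }
  do.call(edit_script, inv)
}

## ---- recombination --------------------------------------------------------

check_segment <- function(s, seg, label) {
  seg <- as.integer(seg)
  if (length(seg) != 2L || anyNA(seg)) {
    stop(label, " must be an integer pair c(first, last)")
  }
  if (seg[1] < 1L || seg[2] < seg[1]) {
    stop(label, ": invalid bounds (zero-length segments are rejected)")
  }
  span <- seg[1]:seg[2]
  if (!all(span %in% s$place)) {
    stop(label, " must lie within the explicit span of its sequence")
  }
  seg
}

#' Recombination between two sequences
#'
#' Swaps the segment `seg_c` of `s_c` with the segment `seg_d` of `s_d` by
#' the E-padding construction: a block of E's the size of the other segment is
#' inserted immediately *before* the segment in the first sequence and
#' immediately *after* it in the second, then one operator vector writes the
#' incoming bases into the E block while erasing the outgoing segment to E's,
#' and the second operator realises the reverse exchange.  When the two
#' segments start at the same place number the two operators are exact
#' componentwise inverses of each other.
#'
#' @param s_c,s_d `seqvec` objects on the same alphabet.
#' @param seg_c,seg_d Integer pairs `c(first, last)` of 1-based place numbers,
#'   inclusive; every place must be an explicit entry.
#' @return A `recombination` object: a list with the padded intermediates
#'   `padded_c`/`padded_d`, the operators `op_c`/`op_d`, and the results
#'   `out_c`/`out_d`.
#' @examples
#' r <- recombine(seqvec("GETAGT"), c(3, 6), seqvec("ATAGCTA"), c(3, 7))
#' seq_text(r$out_c, "explicit")
#' @export
recombine <- function(s_c, seg_c, s_d, seg_d) {
  stopifnot(inherits(s_c, "seqvec"), inherits(s_d, "seqvec"))
  if (s_c$alphabet != s_d$alphabet) stop("alphabet mismatch between sequences")
  seg_c <- check_segment(s_c, seg_c, "seg_c")
  seg_d <- check_segment(s_d, seg_d, "seg_d")
  len_c <- seg_c[2] - seg_c[1] + 1L
  len_d <- seg_d[2] - seg_d[1] + 1L
  idx_c <- s_c$index[match(seg_c[1]:seg_c[2], s_c$place)]
  idx_d <- s_d$index[match(seg_d[1]:seg_d[2], s_d$place)]

  padded_c <- insert_E(s_c, seg_c[1] - 1L, len_d)
  padded_d <- insert_E(s_d, seg_d[2], len_c)

  # write the incoming segment into the E block, erase the outgoing one
  op_c <- new_opvec(
    c(seg_c[1] - 1L + seq_len(len_d), seg_c[1] - 1L + len_d + seq_len(len_c)),
    c(idx_d, (5L - idx_c) %% 5L)
  )
  op_d <- new_opvec(
    c(seg_d[1] - 1L + seq_len(len_d), seg_d[2] + seq_len(len_c)),
    c((5L - idx_d) %% 5L, idx_c)
  )

  structure(
    list(
      padded_c = padded_c, padded_d = padded_d,
      op_c = op_c, op_d = op_d,
      out_c = op_apply(padded_c, op_c),
      out_d = op_apply(padded_d, op_d)
    ),
    class = "recombination"
  )
}

#' @export
print.recombination <- function(x, ...) {
  cat("<recombination>\n")
  cat("  out_c:", seq_text(x$out_c, "explicit"), "\n")
  cat("  out_d:", seq_text(x$out_d, "explicit"), "\n")
  invisible(x)
}

## ---- central dogma --------------------------------------------------------

#' Transcription relabel (DNA to RNA)
#'
#' Changes the alphabet tag from DNA to RNA so index 3 renders as U instead
#' of T; indices, places and direction are unchanged.
#'
#' @param s A DNA `seqvec`.
#' @return An RNA `seqvec`.
#' @export
transcribe <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  if (s$alphabet != "DNA") stop("transcribe() expects a DNA sequence")
  new_seqvec(s$place, s$index, "RNA", s$direction)
}

#' Intron removal by E substitution
#'
#' Replaces every base inside each intron interval by an explicit E; place
#' numbers are unchanged, so downstream coordinates are preserved until
#' [mature()] renumbers.
#'
#' @param s An RNA `seqvec` (pre-mRNA).
#' @param introns A list of integer pairs `c(first, last)` (or a 2-column
#'   matrix), inclusive, 1-based in the transcript's place numbers; intervals
#'   must be disjoint and within the explicit span.
#' @return An RNA `seqvec`.
#' @export
splice <- function(s, introns = list()) {
  stopifnot(inherits(s, "seqvec"))
  if (s$alphabet != "RNA") stop("splice() expects an RNA sequence")
  if (is.matrix(introns)) introns <- asplit(introns, 1)
  if (length(introns) == 0L) return(s)
  ivs <- lapply(introns, function(iv) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] < 1L || iv[2] < iv[1]) {
      stop("each intron must be an integer pair c(first, last)")
    }
    iv
  })
  span <- if (length(s$place)) max(s$place) else 0L
  covered <- unlist(lapply(ivs, function(iv) iv[1]:iv[2]))
  if (anyDuplicated(covered)) stop("intron intervals overlap")
  if (any(covered > span)) stop("intron interval outside the explicit span")
  idx <- s$index
  idx[s$place %in% covered] <- 0L
  new_seqvec(s$place, idx, s$alphabet, s$direction)
}

#' Maturation: delete all explicit E's and renumber
#'
#' The mature mRNA is the [angle()] normalisation of the spliced transcript:
#' all explicit non-trailing E's are deleted simultaneously and the surviving
#' bases renumbered `1..N`.
#'
#' @param s An RNA `seqvec`.
#' @return An RNA `seqvec` with dense places.
#' @export
mature <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  if (s$alphabet != "RNA") stop("mature() expects an RNA sequence")
  angle(s)
}

#' Central-dogma pipeline
#'
#' Chains the morphisms: complement (antisense strand), transcription
#' (T to U relabel), intron splicing (bases to explicit E's) and maturation
#' (delete E's, renumber).
#'
#' @param s A DNA `seqvec`.
#' @param introns Intron intervals in the transcript's place numbers, passed
#'   to [splice()].
#' @param complement If `TRUE` (default) the transcript is the complement of
#'   `s`; if `FALSE` the sense strand is transcribed directly.
#' @return A `central_dogma` object: a list of the stages `dna`, `antisense`,
#'   `pre_mrna`, `spliced` and `mature`.
#' @examples
#' cd <- central_dogma(seqvec("TCATEAGCTGA"), introns = list(c(2, 4)))
#' seq_text(cd$mature)  # "AUCGACU"
#' @export
central_dogma <- function(s, introns = list(), complement = TRUE) {
  stopifnot(inherits(s, "seqvec"))
  if (s$alphabet != "DNA") stop("central_dogma() expects a DNA sequence")
  antisense <- if (complement) complement_seq(s) else s
  pre <- transcribe(antisense)
  spl <- splice(pre, introns)
  structure(
    list(dna = s, antisense = antisense, pre_mrna = pre,
         spliced = spl, mature = mature(spl)),
    class = "central_dogma"
  )
}

#' @export
print.central_dogma <- function(x, ...) {
  cat("<central_dogma>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-9s %s\n", nm, seq_text(x[[nm]], "explicit")))
  }
  invisible(x)
}

#' Codon partition of a mature sequence
#'
#' Groups the conventional letters into triplets after skipping `frame`
#' leading letters; the skipped letters form their own leading group, and the
#' final group may be shorter than three.
#'
#' @param s A matured `seqvec`: no explicit E may precede the last real base.
#' @param frame Reading-frame offset, `0`, `1` or `2`.
#' @return Character vector of letter groups (empty for an empty sequence).
#' @examples
#' m <- seqvec("AUCGACU")
#' codon_partition(m, 0)  # "AUC" "GAC" "U"
#' codon_partition(m, 1)  # "A" "UCG" "ACU"
#' @export
codon_partition <- function(s, frame = 0L) {
  stopifnot(inherits(s, "seqvec"))
  frame <- as.integer(frame)
  if (length(frame) != 1L || !frame %in% 0:2) stop("frame must be 0, 1 or 2")
  real <- s$place[s$index != 0L]
  if (length(real)) {
    interior_E <- s$place[s$index == 0L & s$place < max(real)]
    if (length(interior_E)) {
      stop("sequence is not matured: explicit interior E at place(s) ",
           paste(interior_E, collapse = ", "))
    }
  }
  letters <- strsplit(seq_text(s, "conventional"), "")[[1]]
  if (length(letters) == 0L) return(character())
  groups <- character()
  if (frame > 0L) {
    groups <- paste(letters[seq_len(min(frame, length(letters)))], collapse = "")
    letters <- letters[-seq_len(min(frame, length(letters)))]
  }
  while (length(letters)) {
    take <- seq_len(min(3L, length(letters)))
    groups <- c(groups, paste(letters[take], collapse = ""))
    letters <- letters[-take]
  }
  groups
}
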