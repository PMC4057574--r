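# Evaluated verifiers for the category and functor laws satisfied by the
# edit morphisms.  Objects: X (DNA), Y (antisense DNA), Z (pre-mRNA),
# Zs (spliced mRNA).  Morphisms realised by operator vectors stay inside the
# componentwise group; the complement (rho), transcription (tau) and splicing
# (j) morphisms change object and are represented as relabel/substitution
# steps, never as operator vectors.

#' Build a morphism record
#'
#' @param tag One of `"f"` (operator vector on X), `"rho"` (complement,
#'   X to Y), `"tau"` (T-to-U relabel, Y to Z), `"g"` (rho then tau, X to Z),
#'   `"h"` (operator vector on Z), `"j"` (intron splicing, Z to Zs).
#' @param realization For `f`/`h`, an [opvec()]; for `j`, a list of intron
#'   intervals; ignored for `rho`, `tau`, `g`.
#' @return A `morphism` object with fields `tag`, `source`, `target` and the
#'   realising function `fn`.
#' @export
morphism <- function(tag = c("f", "rho", "tau", "g", "h", "j"),
                     realization = NULL) {
  tag <- match.arg(tag)
  rec <- switch(tag,
    f = {
      stopifnot(inherits(realization, "opvec"))
      list(source = "X", target = "X",
           fn = function(s) op_apply(s, realization))
    },
    rho = list(source = "X", target = "Y", fn = complement_seq),
    tau = list(source = "Y", target = "Z", fn = transcribe),
    g = list(source = "X", target = "Z",
             fn = function(s) transcribe(complement_seq(s))),
    h = {
      stopifnot(inherits(realization, "opvec"))
      list(source = "Z", target = "Z",
           fn = function(s) op_apply(s, realization))
    },
    j = list(source = "Z", target = "Zs",
             fn = function(s) splice(s, realization))
  )
  structure(c(list(tag = tag, realization = realization), rec),
            class = "morphism")
}

#' @export
print.morphism <- function(x, ...) {
  cat(sprintf("<morphism %s : %s -> %s>\n", x$tag, x$source, x$target))
  invisible(x)
}

object_alphabet <- function(object) {
  if (object %in% c("X", "Y")) "DNA" else "RNA"
}

#' Compose two morphisms
#'
#' @param m1,m2 `morphism` objects with `m1$target == m2$source`.
#' @return A composite `morphism` applying `m1` then `m2`.
#' @export
compose_morphisms <- function(m1, m2) {
  stopifnot(inherits(m1, "morphism"), inherits(m2, "morphism"))
  if (m1$target != m2$source) {
    stop("morphisms not composable: ", m1$tag, " targets ", m1$target,
         " but ", m2$tag, " sources from ", m2$source)
  }
  f1 <- m1$fn
  f2 <- m2$fn
  structure(
    list(tag = paste(m1$tag, m2$tag, sep = "."), realization = NULL,
         source = m1$source, target = m2$target,
         fn = function(s) f2(f1(s))),
    class = "morphism"
  )
}

#' Check the identity laws for a morphism
#'
#' Verifies on every sample that composing with the identity operator vector
#' before and after leaves the morphism's action unchanged.  Passing a
#' non-identity `identity_op` provides a negative control.
#'
#' @param m A `morphism`.
#' @param samples List of `seqvec`s on `m`'s source object's alphabet.
#' @param identity_op The candidate identity, by default the empty [opvec()].
#' @return A list with `pass` (logical) and `failures` (sample indices).
#' @export
check_identity_laws <- function(m, samples, identity_op = opvec()) {
  stopifnot(inherits(m, "morphism"), inherits(identity_op, "opvec"))
  src_alpha <- object_alphabet(m$source)
  fails <- integer()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (s$alphabet != src_alpha) {
      stop("sample ", i, " is not on the source object's alphabet (",
           src_alpha, ")")
    }
    direct <- m$fn(s)
    pre <- m$fn(op_apply(s, identity_op))
    post <- op_apply(direct, identity_op)
    if (!seq_equal(pre, direct, ignore_explicit_E = TRUE) ||
        !seq_equal(post, direct, ignore_explicit_E = TRUE)) {
      fails <- c(fails, i)
    }
  }
  list(pass = length(fails) == 0L, failures = fails)
}

#' Check associativity of a three-morphism chain
#'
#' Evaluates `(m1 then m2) then m3` against `m1 then (m2 then m3)` on every
#' sample; the chain must be composable.
#'
#' @param m1,m2,m3 `morphism` objects.
#' @param samples List of `seqvec`s on `m1`'s source alphabet.
#' @return A list with `pass` and `failures`.
#' @export
check_associativity <- function(m1, m2, m3, samples) {
  left <- compose_morphisms(compose_morphisms(m1, m2), m3)
  right <- compose_morphisms(m1, compose_morphisms(m2, m3))
  fails <- integer()
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    if (!seq_equal(left$fn(s), right$fn(s))) fails <- c(fails, i)
  }
  list(pass = length(fails) == 0L, failures = fails)
}

#' Functor into the rotational notation
#'
#' Maps each component of an operator vector to its rotational alias
#' (`n` to `w0`, `r` to `w1`, `u` to `w2`, `d` to `w3`, `l` to `w4`),
#' rendering a dense token vector.  [opvec_from_rotational()] inverts the
#' rendering.
#'
#' @param B An [opvec()].
#' @param n Dense length; defaults to the largest stored place.
#' @return Character vector of `w`-tokens of length `n`.
#' @export
functor_to_rotational <- function(B, n = if (length(B$place)) max(B$place) else 0L) {
  op_tokens(B, "rotational", n)
}

#' @rdname functor_to_rotational
#' @param tokens Character vector of `w`-tokens (place = position).
#' @export
opvec_from_rotational <- function(tokens) {
  opvec(seq_along(tokens), tokens)
}

#' Check the functor laws for the rotational rendering
#'
#' Verifies that the functor preserves composition
#' (`F(B1 * B2) = F(B1) * F(B2)` componentwise) and identities
#' (`F` of the empty operator is all-`w0`), and that it is a bijection on the
#' 25 component pairs.  `component_map` permutes the rotational indices and
#' serves as a negative-control hook.
#'
#' @param B1,B2 [opvec()] objects.
#' @param component_map Integer vector of length 5 mapping exponent `k` to the
#'   rendered rotational index; the default is the identity map `0:4`.
#' @return A list with `pass` and the individual law results.
#' @export
check_functor_laws <- function(B1, B2, component_map = 0:4) {
  stopifnot(inherits(B1, "opvec"), inherits(B2, "opvec"))
  if (length(component_map) != 5L) stop("component_map must have length 5")
  n <- max(c(B1$place, B2$place, 1L))
  render <- function(B) {
    k <- integer(n)
    k[B$place[B$place <= n]] <- B$exponent[B$place <= n]
    paste0("w", component_map[k + 1L])
  }
  widx <- function(tok) as.integer(substr(tok, 2, 2))
  lhs <- render(op_compose(B1, B2))
  rhs <- paste0("w", (widx(render(B1)) + widx(render(B2))) %% 5L)
  composition <- identical(lhs, rhs)
  identity_law <- all(render(opvec()) == "w0")
  # componentwise exhaustive check over all 25 exponent pairs
  comp_pairs <- TRUE
  for (a in 0:4) for (b in 0:4) {
    fa <- component_map[a + 1L]
    fb <- component_map[b + 1L]
    fab <- component_map[(a + b) %% 5L + 1L]
    if (fab != (fa + fb) %% 5L) comp_pairs <- FALSE
  }
  bijection <- !anyDuplicated(component_map)
  list(pass = composition && identity_law && comp_pairs && bijection,
       composition = composition, identity = identity_law,
       component_pairs = comp_pairs, bijection = bijection)
}
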