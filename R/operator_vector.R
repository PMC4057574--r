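# Operator vectors: componentwise tuples of shift-group elements acting
# place-by-place on sequence vectors.  Only non-identity components are
# stored; every absent place is the identity n.

new_opvec <- function(place = integer(), exponent = integer()) {
  place <- as.integer(place)
  exponent <- as.integer(exponent)
  if (length(place) != length(exponent)) stop("place/exponent length mismatch")
  if (any(place < 1L)) stop("place numbers must be positive integers")
  keep <- exponent %% 5L != 0L
  place <- place[keep]
  exponent <- exponent[keep] %% 5L
  if (anyDuplicated(place)) stop("duplicate place numbers in operator vector")
  o <- order(place)
  structure(list(place = place[o], exponent = exponent[o]), class = "opvec")
}

#' Construct an operator vector
#'
#' An operator vector assigns a shift-group element to each place number;
#' places not mentioned carry the identity `n`.  Composition, inversion and
#' application to sequences are all componentwise.
#'
#' @param place Integer vector of 1-based place numbers.
#' @param op Matching vector of group elements: exponents, linear aliases,
#'   `"w0".."w4"`, or `"x[a,b]"` tokens (anything [z5()] accepts).  Identity
#'   components are dropped.
#' @return An `opvec` object.
#' @examples
#' opvec(4:5, c("u", "d"))
#' @export
opvec <- function(place = integer(), op = integer()) {
  new_opvec(place, z5_exponent(z5(op)))
}

#' Parse a dense operator token string
#'
#' Convenience constructor: tokens separated by whitespace are assigned
#' places `1..L`; identity (`n`/`w0`) components are dropped.
#'
#' @param text A string such as `"n n n u d n n"`.
#' @return An `opvec` object.
#' @examples
#' opvec_parse("n n n u d n n")
#' @export
opvec_parse <- function(text) {
  tok <- strsplit(trimws(paste(text, collapse = " ")), "[[:space:]|]+")[[1]]
  tok <- tok[nzchar(tok)]
  opvec(seq_along(tok), tok)
}

#' @export
print.opvec <- function(x, ...) {
  cat(sprintf("<opvec  %d non-identity component(s)>\n", length(x$place)))
  if (length(x$place)) {
    cat(" ", paste0(z5_alias(z5(x$exponent)), x$place, collapse = " "), "\n")
  }
  invisible(x)
}

#' Render an operator vector as tokens
#'
#' @param B An `opvec`.
#' @param notation Passed to [z5_alias()].
#' @param n Length of the dense rendering; defaults to the largest stored
#'   place.  Identity components render as `"n"`, `"w0"` or `"x[0,0]"`.
#' @return Character vector of length `n`, one token per place.
#' @export
op_tokens <- function(B, notation = c("linear", "rotational", "wallpaper"),
                      n = if (length(B$place)) max(B$place) else 0L) {
  stopifnot(inherits(B, "opvec"))
  notation <- match.arg(notation)
  k <- integer(n)
  k[B$place[B$place <= n]] <- B$exponent[B$place <= n]
  z5_alias(z5(k), notation)
}

#' Compose two operator vectors
#'
#' Componentwise group composition over the union of supports; components
#' composing to the identity are dropped.  Commutative and associative, with
#' the empty operator as identity.
#'
#' @param B1,B2 `opvec` objects.
#' @return An `opvec`.
#' @export
op_compose <- function(B1, B2) {
  stopifnot(inherits(B1, "opvec"), inherits(B2, "opvec"))
  places <- sort(unique(c(B1$place, B2$place)))
  e1 <- integer(length(places))
  e2 <- integer(length(places))
  e1[match(B1$place, places)] <- B1$exponent
  e2[match(B2$place, places)] <- B2$exponent
  new_opvec(places, (e1 + e2) %% 5L)
}

#' Invert an operator vector
#'
#' Componentwise inverse: `op_compose(B, op_inverse(B))` is the identity.
#'
#' @param B An `opvec`.
#' @return An `opvec`.
#' @export
op_inverse <- function(B) {
  stopifnot(inherits(B, "opvec"))
  new_opvec(B$place, (5L - B$exponent) %% 5L)
}

#' Apply an operator vector to a sequence
#'
#' At each place the base index shifts by the component exponent mod 5.
#' Operators may act at implicit places (the background E), materialising an
#' explicit base there; explicit entries mapped to E are kept as explicit E's
#' so that later deletions can track them.
#'
#' @param s A `seqvec`.
#' @param B An `opvec`.
#' @return A `seqvec` with the same alphabet and direction as `s`.
#' @export
op_apply <- function(s, B) {
  stopifnot(inherits(s, "seqvec"), inherits(B, "opvec"))
  places <- sort(unique(c(s$place, B$place)))
  idx <- integer(length(places))
  expn <- integer(length(places))
  idx[match(s$place, places)] <- s$index
  expn[match(B$place, places)] <- B$exponent
  new_idx <- (idx + expn) %% 5L
  keep <- places %in% s$place | new_idx != 0L
  new_seqvec(places[keep], new_idx[keep], s$alphabet, s$direction)
}

#' Operator vector transforming one sequence into another
#'
#' Strictly positional diff over the union of supports (absent entries count
#' as E): the component at each place is the group element carrying the source
#' base to the target base, i.e. exponent `(to - from) mod 5`.  No indel
#' alignment is attempted; insert or delete E's first if places must shift.
#'
#' @param s_from,s_to `seqvec` objects on the same alphabet.
#' @return An `opvec` with `op_apply(s_from, .)` equal to `s_to` up to
#'   explicit/implicit E status.
#' @export
op_diff <- function(s_from, s_to) {
  stopifnot(inherits(s_from, "seqvec"), inherits(s_to, "seqvec"))
  if (s_from$alphabet != s_to$alphabet) {
    stop("cannot diff sequences on different alphabets")
  }
  places <- sort(unique(c(s_from$place, s_to$place)))
  f <- integer(length(places))
  t <- integer(length(places))
  f[match(s_from$place, places)] <- s_from$index
  t[match(s_to$place, places)] <- s_to$index
  new_opvec(places, (t - f) %% 5L)
}

#' Operator vector realising the complement
#'
#' At every explicit place holding a base with index `m` the component has
#' exponent `(-2m) mod 5`, which carries index `m` to `(5 - m) mod 5`;
#' E's (explicit or implicit) contribute the identity.
#'
#' @param s A `seqvec`.
#' @return An `opvec` with `op_apply(s, .)` the base-wise complement of `s`.
#' @export
complement_operator <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  new_opvec(s$place, (-2L * s$index) %% 5L)
}

#' Complement of a sequence vector
#'
#' Every explicit base is replaced by its complement ([complement_base()]);
#' place numbers and their order are unchanged and the direction label is
#' flipped (the complement strand runs antiparallel).  Use [seq_reverse()]
#' separately if reversed coordinates are wanted.
#'
#' @param s A `seqvec`.
#' @return A `seqvec`.
#' @examples
#' seq_text(complement_seq(seqvec("A1 T2 C3 E4 G5 T6")), "explicit")
#' @export
complement_seq <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  dir <- if (s$direction == "5to3") "3to5" else "5to3"
  new_seqvec(s$place, (5L - s$index) %% 5L, s$alphabet, dir)
}
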