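# Sparse place-indexed sequence vectors.  A seqvec stores only its explicit
# entries (which may be explicit E's); every place number absent from the
# entries is an implicit E, including the notional infinite trailing tail.

new_seqvec <- function(place = integer(), index = integer(),
                       alphabet = "DNA", direction = "5to3") {
  place <- as.integer(place)
  index <- as.integer(index)
  if (length(place) != length(index)) stop("place/index length mismatch")
  if (anyNA(place) || anyNA(index)) stop("NA in seqvec entries")
  if (any(place < 1L)) stop("place numbers must be positive integers")
  if (anyDuplicated(place)) stop("duplicate place numbers")
  if (any(index < 0L | index > 4L)) stop("base indices must lie in 0..4")
  o <- order(place)
  structure(
    list(place = place[o], index = index[o],
         alphabet = alphabet, direction = direction),
    class = "seqvec"
  )
}

#' Construct a sequence vector
#'
#' A sequence vector is a sparse map from 1-based place numbers to explicit
#' bases over an implicit infinite background of `E`'s.  An `E` stored at a
#' place (an *explicit* E) is tracked through edits; a place with no entry is
#' an *implicit* E.
#'
#' @param x Either a plain letter string such as `"CTGATAAC"` (places assigned
#'   `1..L`; `E` letters become explicit E entries) or a spaced letter+place
#'   token string such as `"C1 T2 E3 G4"` (a trailing `"|E..."` tail marker is
#'   ignored).  Whitespace and case are normalised.
#' @param alphabet `"DNA"` or `"RNA"`; if missing, inferred from the letters
#'   (`U` implies RNA).
#' @param direction `"5to3"` (default) or `"3to5"`, a label only.
#' @return A `seqvec` object.
#' @examples
#' seqvec("CTGATAAC")
#' seqvec("C1 T2 E3 G4 A5 T6 E7 E8 A9 A10 C11")
#' @export
seqvec <- function(x = "", alphabet = NULL, direction = c("5to3", "3to5")) {
  direction <- match.arg(direction)
  stopifnot(is.character(x))
  x <- toupper(paste(x, collapse = " "))
  x <- gsub("\\|E\\.\\.\\.", " ", x)
  x <- trimws(x)
  if (!nzchar(x)) {
    if (is.null(alphabet)) alphabet <- "DNA"
    return(new_seqvec(alphabet = match.arg(alphabet, c("DNA", "RNA")),
                      direction = direction))
  }
  if (grepl("[0-9]", x)) {
    tok <- strsplit(x, "[[:space:]|]+")[[1]]
    tok <- tok[nzchar(tok)]
    m <- regmatches(tok, regexec("^([A-Z])([0-9]+)$", tok))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) stop("malformed token(s): ", paste(tok[bad], collapse = ", "))
    letters <- vapply(m, `[`, "", 2L)
    places <- as.integer(vapply(m, `[`, "", 3L))
  } else {
    letters <- strsplit(gsub("[[:space:]]", "", x), "")[[1]]
    places <- seq_along(letters)
  }
  if (is.null(alphabet)) alphabet <- infer_alphabet(letters)
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  new_seqvec(places, base_index(letters, alphabet), alphabet, direction)
}

#' @export
print.seqvec <- function(x, ...) {
  cat(sprintf("<seqvec %s %s  N = %d>\n", x$alphabet, x$direction, n_bases(x)))
  cat(" ", seq_text(x, "explicit"), "\n")
  invisible(x)
}

#' Letters of the explicit entries
#' @param s A `seqvec`.
#' @return Character vector of letters named by place number.
#' @export
seq_letters <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  stats::setNames(base_letter(s$index, s$alphabet), s$place)
}

#' Explicit place numbers
#' @param s A `seqvec`.
#' @return Integer vector of places holding explicit entries.
#' @export
seq_places <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  s$place
}

#' Number of real bases
#'
#' Counts explicit non-E entries; explicit and implicit E's are excluded, so
#' the value is invariant under all E bookkeeping operations.
#'
#' @param s A `seqvec`.
#' @return A single integer.
#' @examples
#' n_bases(seqvec("CTGATAAC"))  # 8
#' @export
n_bases <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  sum(s$index != 0L)
}

#' Insert explicit E's
#'
#' Inserts `count` explicit E's at places `after_place + 1, ...,
#' after_place + count`; every existing entry beyond `after_place` shifts up
#' by `count`.
#'
#' @param s A `seqvec`.
#' @param after_place Non-negative integer; `0` inserts at the front.
#' @param count Positive integer number of E's.
#' @return A `seqvec`.
#' @examples
#' insert_E(seqvec("ACGT"), 1, 1)  # A1 E2 C3 G4 T5
#' @export
insert_E <- function(s, after_place, count = 1L) {
  stopifnot(inherits(s, "seqvec"))
  after_place <- as.integer(after_place)
  count <- as.integer(count)
  if (length(after_place) != 1L || after_place < 0L) {
    stop("after_place must be a single non-negative integer")
  }
  if (length(count) != 1L || count < 1L) stop("count must be a positive integer")
  place <- s$place
  place[place > after_place] <- place[place > after_place] + count
  new_seqvec(
    c(place, after_place + seq_len(count)),
    c(s$index, integer(count)),
    s$alphabet, s$direction
  )
}

#' Delete explicit E's
#'
#' Removes the named places, which must each hold an explicit E, and decreases
#' higher place numbers by the number of removed places below them.
#'
#' @param s A `seqvec`.
#' @param places Integer vector of places to delete (each an explicit E).
#' @return A `seqvec`.
#' @export
delete_E <- function(s, places) {
  stopifnot(inherits(s, "seqvec"))
  places <- as.integer(places)
  if (length(places) == 0L) return(s)
  if (anyDuplicated(places)) stop("duplicate places in deletion set")
  hit <- match(places, s$place)
  if (anyNA(hit)) {
    stop("place(s) not explicit entries: ",
         paste(places[is.na(hit)], collapse = ", "))
  }
  if (any(s$index[hit] != 0L)) {
    stop("place(s) do not hold an explicit E: ",
         paste(places[s$index[hit] != 0L], collapse = ", "))
  }
  keep_place <- s$place[-hit]
  keep_index <- s$index[-hit]
  shift <- vapply(keep_place, function(p) sum(places < p), 1L)
  new_seqvec(keep_place - shift, keep_index, s$alphabet, s$direction)
}

#' Demote explicit E's to implicit (brace operator)
#'
#' Removes explicit E entries from the map while retaining every other entry's
#' place number, leaving sparse index gaps.  Idempotent.
#'
#' @param s A `seqvec`.
#' @return A `seqvec` with no explicit E entries.
#' @export
braces <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  keep <- s$index != 0L
  new_seqvec(s$place[keep], s$index[keep], s$alphabet, s$direction)
}

#' Delete E's and renumber (angle operator)
#'
#' Removes all explicit E's and index gaps, renumbering the surviving bases
#' contiguously `1..N`.  The result is the conventional sequence in vector
#' form.
#'
#' @param s A `seqvec`.
#' @return A `seqvec` with dense places `1..N`.
#' @examples
#' angle(seqvec("C1 T2 E3 G4 A5 T6 E7 E8 A9 A10 C11"))
#' @export
angle <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  keep <- s$index != 0L
  new_seqvec(seq_len(sum(keep)), s$index[keep], s$alphabet, s$direction)
}

#' Iterated angle operator
#'
#' @param s A `seqvec`.
#' @param t Non-negative integer; `t = 0` returns `s` unchanged, `t >= 1`
#'   applies [angle()] `t` times (idempotent after the first application
#'   unless edits are interleaved).
#' @return A `seqvec`.
#' @export
angle_t <- function(s, t) {
  stopifnot(inherits(s, "seqvec"))
  t <- as.integer(t)
  if (length(t) != 1L || t < 0L) stop("t must be a single non-negative integer")
  for (i in seq_len(t)) s <- angle(s)
  s
}

#' Reverse a sequence vector
#'
#' Reverses base order over the span `1..max(place)` (implicit gaps map
#' symmetrically) and flips the direction label.
#'
#' @param s A `seqvec`.
#' @return A `seqvec`.
#' @examples
#' seq_reverse(seqvec("CGACTAT"))
#' @export
seq_reverse <- function(s) {
  stopifnot(inherits(s, "seqvec"))
  dir <- if (s$direction == "5to3") "3to5" else "5to3"
  if (length(s$place) == 0L) {
    return(new_seqvec(alphabet = s$alphabet, direction = dir))
  }
  m <- max(s$place)
  new_seqvec(m + 1L - s$place, s$index, s$alphabet, dir)
}

#' @method rev seqvec
#' @export
rev.seqvec <- function(x) seq_reverse(x)

#' Render a sequence vector as text
#'
#' @param s A `seqvec`.
#' @param mode `"conventional"` drops all E's and gaps and emits the plain
#'   base string; `"explicit"` lists every explicit entry as letter+place and
#'   appends the `"|E..."` tail marker.
#' @return A single string.
#' @examples
#' seq_text(seqvec("A1 C2 G3 E4 T5"), "conventional")  # "ACGT"
#' @export
seq_text <- function(s, mode = c("conventional", "explicit")) {
  stopifnot(inherits(s, "seqvec"))
  mode <- match.arg(mode)
  if (mode == "conventional") {
    keep <- s$index != 0L
    paste(base_letter(s$index[keep], s$alphabet), collapse = "")
  } else {
    tok <- paste0(base_letter(s$index, s$alphabet), s$place)
    trimws(paste(paste(tok, collapse = " "), "|E..."))
  }
}

#' @export
as.character.seqvec <- function(x, ...) seq_text(x, "conventional")

#' Compare two sequence vectors
#'
#' @param a,b `seqvec` objects.
#' @param ignore_direction If `TRUE`, the direction labels are not compared.
#' @param ignore_explicit_E If `TRUE`, explicit E entries are disregarded, so
#'   vectors equal "up to explicit/implicit E status" compare equal.
#' @return `TRUE` or `FALSE`.
#' @export
seq_equal <- function(a, b, ignore_direction = FALSE, ignore_explicit_E = FALSE) {
  stopifnot(inherits(a, "seqvec"), inherits(b, "seqvec"))
  if (a$alphabet != b$alphabet) return(FALSE)
  if (!ignore_direction && a$direction != b$direction) return(FALSE)
  if (ignore_explicit_E) {
    a <- braces(a)
    b <- braces(b)
  }
  identical(a$place, b$place) && identical(a$index, b$index)
}

#' Seeded random sequence vector
#'
#' Fixture generator: letters are uniform over the four real bases, and each
#' position independently becomes an explicit E with probability
#' `p_explicit_E`.  Deterministic for a fixed seed; with `seed = NULL` the
#' current RNG stream is used.
#'
#' @param length Non-negative integer number of positions.
#' @param p_explicit_E Probability in `[0, 1]` of an explicit E per position.
#' @param alphabet `"DNA"` or `"RNA"`.
#' @param direction `"5to3"` or `"3to5"`.
#' @param seed Optional integer seed (applied locally, leaving the global RNG
#'   untouched).
#' @return A `seqvec` with dense places `1..length`.
#' @export
random_seqvec <- function(length, p_explicit_E = 0, alphabet = c("DNA", "RNA"),
                          direction = "5to3", seed = NULL) {
  alphabet <- match.arg(alphabet)
  length <- as.integer(length)
  if (length < 0L) stop("length must be non-negative")
  if (p_explicit_E < 0 || p_explicit_E > 1) stop("p_explicit_E must lie in [0, 1]")
  draw <- function() {
    idx <- sample(1:4, length, replace = TRUE)
    idx[stats::runif(length) < p_explicit_E] <- 0L
    idx
  }
  idx <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  new_seqvec(seq_len(length), idx, alphabet, direction)
}
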