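# The order-5 shift algebra on {n, r, u, d, l} and its action on the
# five-letter base set {E, C, A, T/U, G}.  Every element is stored canonically
# as an exponent k of the generator r (k in 0..4); the aliases u = r^2,
# d = r^3, l = r^4 and the rotational (w_m) and wallpaper (x[a,b]) notations
# are parse/print forms only.

Z5_ALIASES <- c("n", "r", "u", "d", "l")

ALPHABETS <- list(
  DNA = c("E", "C", "A", "T", "G"),
  RNA = c("E", "C", "A", "U", "G")
)

#' Construct elements of the order-5 shift group
#'
#' The five shift operations on the five-letter base lattice form a cyclic
#' group of order five generated by `r` (one step right along a lattice row),
#' with `u = r^2`, `d = r^3`, `l = r^4` and identity `n`.  Elements are stored
#' canonically as exponents of `r`.
#'
#' @param x An integer vector of exponents (reduced mod 5), an existing `z5`
#'   object, or a character vector of tokens in any of the three notations:
#'   linear (`"n"`, `"r"`, `"u"`, `"d"`, `"l"`), rotational (`"w0"` ... `"w4"`),
#'   or wallpaper (`"x[a,b]"` with signed integers `a`, `b`).
#' @return A `z5` object: an integer vector of exponents in `0..4`.
#' @examples
#' z5("r") * z5("r")      # u
#' z5("x[2,11]")          # l
#' z5(0:4)
#' @export
z5 <- function(x = integer()) {
  if (inherits(x, "z5")) return(x)
  if (is.character(x)) {
    k <- parse_z5_tokens(x)
  } else {
    if (!is.numeric(x)) stop("cannot interpret ", class(x)[1], " as a z5 element")
    k <- as.integer(round(x))
  }
  structure(k %% 5L, class = "z5")
}

parse_z5_tokens <- function(tok) {
  out <- integer(length(tok))
  for (i in seq_along(tok)) {
    t <- tok[i]
    if (t %in% Z5_ALIASES) {
      out[i] <- match(t, Z5_ALIASES) - 1L
    } else if (grepl("^w[0-4]$", t)) {
      out[i] <- as.integer(substr(t, 2, 2))
    } else if (grepl("^x\\[-?[0-9]+,-?[0-9]+\\]$", t)) {
      ab <- as.integer(strsplit(gsub("^x\\[|\\]$", "", t), ",", fixed = TRUE)[[1]])
      out[i] <- (ab[1] + 2L * ab[2]) %% 5L
    } else {
      stop("unrecognised group-element token: '", t, "'")
    }
  }
  out
}

#' @export
print.z5 <- function(x, ...) {
  cat("<z5>", if (length(x)) paste(z5_alias(x), collapse = " ") else "(empty)", "\n")
  invisible(x)
}

#' @method format z5
#' @export
format.z5 <- function(x, ...) z5_alias(x)

#' Compose two shift operations
#'
#' Group composition: exponents add modulo 5.  Commutative and associative.
#' Also available as `g1 * g2`.
#'
#' @param g1,g2 `z5` objects (or anything [z5()] accepts); recycled.
#' @return A `z5` object.
#' @examples
#' z5_compose("r", "r")  # u
#' z5_compose("d", "d")  # r
#' @export
z5_compose <- function(g1, g2) {
  z5((unclass(z5(g1)) + unclass(z5(g2))) %% 5L)
}

#' Invert a shift operation
#'
#' `r` and `l` are mutually inverse, as are `u` and `d`; `n` is self-inverse.
#'
#' @param g A `z5` object (or token/exponent).
#' @return A `z5` object with `z5_compose(g, z5_inverse(g))` the identity.
#' @export
z5_inverse <- function(g) {
  z5((5L - unclass(z5(g))) %% 5L)
}

#' @export
Ops.z5 <- function(e1, e2) {
  switch(.Generic,
    "*" = z5_compose(e1, e2),
    "^" = z5(unclass(z5(e1)) * as.integer(e2)),
    "==" = unclass(z5(e1)) == unclass(z5(e2)),
    "!=" = unclass(z5(e1)) != unclass(z5(e2)),
    stop("operation '", .Generic, "' not defined for z5 objects")
  )
}

#' Exponent of a group element
#'
#' @param g A `z5` object (or token/exponent).
#' @return Integer vector of canonical exponents of the generator `r`, in `0..4`.
#' @export
z5_exponent <- function(g) as.integer(unclass(z5(g)))

#' Build a group element from wallpaper displacement coordinates
#'
#' `x[a,b]` denotes `a` steps right composed with `b` steps up on the lattice,
#' i.e. `r^a * u^b`; since `u = r^2` its canonical exponent is `(a + 2b) mod 5`.
#'
#' @param a,b Integer vectors (negative values allowed); recycled.
#' @return A `z5` object.
#' @examples
#' z5_from_xy(2, 0)   # u
#' z5_from_xy(1, 1)   # d
#' @export
z5_from_xy <- function(a, b) {
  z5((as.integer(a) + 2L * as.integer(b)) %% 5L)
}

#' Render a group element in one of the three notations
#'
#' @param g A `z5` object (or token/exponent).
#' @param notation `"linear"` (`n`, `r`, `u`, `d`, `l`), `"rotational"`
#'   (`w0` ... `w4`), or `"wallpaper"` (canonical `x[k,0]`).
#' @return A character vector of tokens.
#' @examples
#' z5_alias(z5("u"), "rotational")  # "w2"
#' @export
z5_alias <- function(g, notation = c("linear", "rotational", "wallpaper")) {
  notation <- match.arg(notation)
  k <- z5_exponent(g)
  switch(notation,
    linear = Z5_ALIASES[k + 1L],
    rotational = paste0("w", k),
    wallpaper = sprintf("x[%d,0]", k)
  )
}

#' All in-cell wallpaper coordinate pairs for a group element
#'
#' Within one 5x5 unit cell there are exactly five pairs `(a, b)` with
#' `a, b` in `0..4` realising any given element as `x[a,b]`.
#'
#' @param g A `z5` object (or token/exponent of length 1).
#' @return A data frame with columns `a` and `b` (five rows).
#' @export
xy_equivalents <- function(g) {
  k <- z5_exponent(z5(g))
  if (length(k) != 1L) stop("xy_equivalents() expects a single element")
  grid <- expand.grid(a = 0:4, b = 0:4)
  grid[(grid$a + 2L * grid$b) %% 5L == k, , drop = FALSE]
}

#' Cayley table of the shift group
#'
#' @return A 5x5 character matrix of linear aliases; `table[i, j]` is the
#'   composition of row element `i` with column element `j`.
#' @export
cayley_table <- function() {
  m <- outer(0:4, 0:4, function(i, j) Z5_ALIASES[(i + j) %% 5L + 1L])
  dimnames(m) <- list(Z5_ALIASES, Z5_ALIASES)
  m
}

## ---- bases ----------------------------------------------------------------

infer_alphabet <- function(letters) {
  if (any(letters == "U")) {
    if (any(letters == "T")) stop("sequence mixes T and U; alphabet is ambiguous")
    "RNA"
  } else {
    "DNA"
  }
}

#' Map base letters to phase indices
#'
#' The five letters correspond bijectively to indices `m` in `0..4`:
#' `E = 0`, `C = 1`, `A = 2`, `T/U = 3`, `G = 4`.
#'
#' @param b Character vector of base letters.
#' @param alphabet `"DNA"` or `"RNA"`; if `NULL`, inferred from the letters
#'   (`U` implies RNA, otherwise DNA).
#' @return Integer vector of indices in `0..4`.
#' @export
base_index <- function(b, alphabet = NULL) {
  b <- toupper(as.character(b))
  if (is.null(alphabet)) alphabet <- infer_alphabet(b)
  alphabet <- match.arg(alphabet, c("DNA", "RNA"))
  m <- match(b, ALPHABETS[[alphabet]]) - 1L
  if (anyNA(m)) {
    bad <- unique(b[is.na(m)])
    stop("letter(s) not in the ", alphabet, " alphabet: ", paste(bad, collapse = ", "))
  }
  m
}

#' Map phase indices to base letters
#'
#' @param m Integer vector of indices (reduced mod 5).
#' @param alphabet `"DNA"` or `"RNA"` (index 3 renders as `T` or `U`).
#' @return Character vector of letters.
#' @export
base_letter <- function(m, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  ALPHABETS[[alphabet]][as.integer(m) %% 5L + 1L]
}

#' Apply a shift operation to a base
#'
#' The group acts on the five letters by adding the exponent to the base's
#' phase index mod 5; e.g. `E` under `r` becomes `C`, under `u` becomes `A`,
#' under `d` becomes `T`, under `l` becomes `G`.
#'
#' @param b Character vector of base letters.
#' @param g A `z5` object (or token/exponent); recycled against `b`.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to infer from `b`.
#' @return Character vector of letters.
#' @examples
#' apply_base("E", "r")  # "C"
#' apply_base("A", "l")  # "C"
#' @export
apply_base <- function(b, g, alphabet = NULL) {
  b <- toupper(as.character(b))
  if (is.null(alphabet)) alphabet <- infer_alphabet(b)
  m <- base_index(b, alphabet)
  base_letter((m + z5_exponent(g)) %% 5L, alphabet)
}

#' Complement of a base
#'
#' The complement of the base with index `m` is the base with index
#' `(5 - m) mod 5`, i.e. the point diametrically opposite through `E` on the
#' lattice: `A` pairs with `T` (or `U`), `C` with `G`, and `E` is self-paired.
#' An involution.
#'
#' @param b Character vector of base letters.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to infer from `b`.
#' @return Character vector of complementary letters.
#' @examples
#' complement_base(c("A", "C", "E"))  # "T" "G" "E"
#' @export
complement_base <- function(b, alphabet = NULL) {
  b <- toupper(as.character(b))
  if (is.null(alphabet)) alphabet <- infer_alphabet(b)
  m <- base_index(b, alphabet)
  base_letter((5L - m) %% 5L, alphabet)
}

#' Phasor representation of a base
#'
#' Each base maps to the fifth root of unity `exp(m * 2i*pi/5)` where `m` is
#' its phase index; shift operations act as rotations by multiples of `2*pi/5`.
#'
#' @param b Character vector of base letters.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to infer from `b`.
#' @return Complex vector on the unit circle.
#' @export
base_phasor <- function(b, alphabet = NULL) {
  m <- base_index(b, alphabet)
  exp(1i * 2 * pi / 5 * m)
}

#' Generator exponent realising a base from E
#'
#' The base with index `m` equals `E` shifted by `r^m`; in the `u`-generated
#' representation the same base is `E` shifted by `u^(3m mod 5)` (forced by
#' `u = r^2`).
#'
#' @param b A single base letter.
#' @param generator `"r"` or `"u"`.
#' @param alphabet `"DNA"`, `"RNA"`, or `NULL` to infer.
#' @return A single integer exponent in `0..4`.
#' @export
base_power <- function(b, generator = c("r", "u"), alphabet = NULL) {
  generator <- match.arg(generator)
  m <- base_index(b, alphabet)
  if (length(m) != 1L) stop("base_power() expects a single letter")
  if (generator == "r") m else (3L * m) %% 5L
}
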