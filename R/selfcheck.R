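# Aggregate self-verification: exhaustive component-level group/functor
# checks plus seeded sequence-level property suites.

axiom_checks_from_table <- function(tab) {
  els <- rownames(tab)
  list(
    group_closure = all(tab %in% els) && length(unique(as.vector(tab))) == 5L,
    group_identity = all(tab["n", ] == colnames(tab)) &&
      all(tab[, "n"] == rownames(tab)),
    group_inverses = all(vapply(els, function(x) {
      sum(tab[x, ] == "n") == 1L
    }, TRUE)),
    group_commutativity = identical(tab, t(tab)),
    group_associativity = all(vapply(els, function(x) {
      all(vapply(els, function(y) {
        all(vapply(els, function(z) {
          tab[tab[x, y], z] == tab[x, tab[y, z]]
        }, TRUE))
      }, TRUE))
    }, TRUE))
  )
}

#' Run the package self-check
#'
#' Runs the exhaustive component-level verifications (group axioms over all
#' 25 compositions and 125 associativity triples, functor laws over all 25
#' component pairs) and seeded sequence-level property suites: diff/apply
#' round trips, complement involution and operator consistency, composition
#' decomposition through the all-E identity sequence, recombination operator
#' inversion, wallpaper-grid step consistency, and lattice displacement
#' identities.
#'
#' @param seed Integer seed for the sampled suites.
#' @param n_cases Number of random cases per sampled suite.
#' @param cayley Composition table to audit; defaults to [cayley_table()]
#'   (an alternative table is a hook for negative-control testing).
#' @return A `selfcheck_report`: list with `seed`, named logical `checks`,
#'   `failed` (names of failing checks) and overall `pass`.
#' @export
selfcheck <- function(seed = 1L, n_cases = 100L, cayley = cayley_table()) {
  checks <- axiom_checks_from_table(cayley)

  checks <- c(checks, withr::with_seed(seed, {
    rnd_seq <- function() random_seqvec(sample(5:30, 1), p_explicit_E = 0.15)
    rnd_op <- function(n = 20L) {
      k <- sample(0:4, n, replace = TRUE)
      opvec(seq_len(n), k)
    }
    ok_diff <- TRUE
    ok_comp <- TRUE
    ok_decomp <- TRUE
    ok_recomb <- TRUE
    ok_functor <- TRUE
    for (i in seq_len(n_cases)) {
      a <- rnd_seq()
      b <- rnd_seq()
      c_ <- rnd_seq()
      if (!seq_equal(op_apply(a, op_diff(a, b)), b,
                     ignore_explicit_E = TRUE)) ok_diff <- FALSE
      if (!seq_equal(complement_seq(complement_seq(a)), a)) ok_comp <- FALSE
      if (!seq_equal(op_apply(a, complement_operator(a)), complement_seq(a),
                     ignore_direction = TRUE, ignore_explicit_E = TRUE)) {
        ok_comp <- FALSE
      }
      lhs <- op_diff(a, c_)
      rhs <- op_compose(op_diff(a, b), op_diff(b, c_))
      if (!seq_equal(op_apply(a, rhs), c_, ignore_explicit_E = TRUE) ||
          !identical(lhs$place, rhs$place) ||
          !identical(lhs$exponent, rhs$exponent)) ok_decomp <- FALSE
      if (!check_functor_laws(rnd_op(), rnd_op())$pass) ok_functor <- FALSE
      if (i <= n_cases %/% 2L) {
        sc <- random_seqvec(12, p_explicit_E = 0)
        sd <- random_seqvec(12, p_explicit_E = 0)
        start <- sample(1:6, 1)
        r <- recombine(sc, c(start, start + sample(0:4, 1)),
                       sd, c(start, start + sample(0:4, 1)))
        inv <- op_inverse(r$op_c)
        if (!identical(inv$place, r$op_d$place) ||
            !identical(inv$exponent, r$op_d$exponent)) ok_recomb <- FALSE
      }
    }
    xy <- sample(-10:10, 2 * n_cases, replace = TRUE)
    gx <- xy[seq_len(n_cases)]
    gy <- xy[n_cases + seq_len(n_cases)]
    ok_grid <- all(
      grid_letter(gx + 1L, gy) == apply_base(grid_letter(gx, gy), "r"),
      grid_letter(gx, gy + 1L) == apply_base(grid_letter(gx, gy), "u"),
      grid_letter(-gx, -gy) == complement_base(grid_letter(gx, gy))
    )
    ab <- expand.grid(a = 0:4, b = 0:4)
    ok_xy <- all(
      z5_from_xy(ab$a + 5L, ab$b) == z5_from_xy(ab$a, ab$b),
      z5_from_xy(ab$a, ab$b + 5L) == z5_from_xy(ab$a, ab$b),
      z5_exponent(z5_from_xy(2L * ab$a, -ab$a)) == 0L,
      z5_exponent(z5_from_xy(ab$a, 2L * ab$a)) == 0L,
      z5_exponent(z5_from_xy(-2L * ab$a, ab$a)) == 0L,
      z5_exponent(z5_from_xy(-ab$a, -2L * ab$a)) == 0L
    )
    list(
      diff_apply_roundtrip = ok_diff,
      complement_consistency = ok_comp,
      composition_decomposition = ok_decomp,
      recombination_inverse = ok_recomb,
      functor_laws = ok_functor,
      grid_step_consistency = ok_grid,
      lattice_identities = ok_xy
    )
  }))

  checks <- lapply(checks, isTRUE)
  structure(
    list(seed = as.integer(seed),
         checks = checks,
         failed = names(checks)[!unlist(checks)],
         pass = all(unlist(checks))),
    class = "selfcheck_report"
  )
}

#' @export
print.selfcheck_report <- function(x, ...) {
  cat(sprintf("<selfcheck seed=%d  %s>\n", x$seed,
              if (x$pass) "PASS" else "FAIL"))
  for (nm in names(x$checks)) {
    cat(sprintf("  %-28s %s\n", nm, if (x$checks[[nm]]) "ok" else "FAILED"))
  }
  invisible(x)
}

#' Serialise a self-check report as stable JSON
#'
#' @param report A `selfcheck_report`.
#' @return A JSON string (deterministic for a fixed seed).
#' @export
selfcheck_json <- function(report) {
  stopifnot(inherits(report, "selfcheck_report"))
  as.character(jsonlite::toJSON(unclass(report), auto_unbox = TRUE))
}
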