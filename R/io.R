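# FASTA and JSON interchange.  FASTA carries conventional or E-explicit
# letter strings (E is a first-class letter here, not an alignment gap); the
# "evec" JSON sidecar serialises full place-number bookkeeping and the
# "editlog" JSON serialises operator vectors.  JSON writers are canonical so
# round-trips are byte-exact.

parse_fasta_record <- function(string, desc, dash_as_E = FALSE) {
  string <- toupper(string)
  if (dash_as_E) string <- gsub("-", "E", string, fixed = TRUE)
  letters <- strsplit(string, "")[[1]]
  ok <- letters %in% c("A", "C", "G", "T", "U", "E")
  if (!all(ok)) {
    stop("illegal character(s) in FASTA record: ",
         paste(unique(letters[!ok]), collapse = ", "))
  }
  if (any(letters == "T") && any(letters == "U")) {
    stop("FASTA record mixes T and U")
  }
  alphabet <- if (grepl("alphabet=RNA", desc, fixed = TRUE)) {
    "RNA"
  } else if (grepl("alphabet=DNA", desc, fixed = TRUE)) {
    "DNA"
  } else if (any(letters == "U")) "RNA" else "DNA"
  direction <- if (grepl("direction=3to5", desc, fixed = TRUE)) "3to5" else "5to3"
  if (length(letters) == 0L) {
    new_seqvec(alphabet = alphabet, direction = direction)
  } else {
    new_seqvec(seq_along(letters), base_index(letters, alphabet),
               alphabet, direction)
  }
}

#' Read sequence vectors from FASTA
#'
#' Letters are restricted to `A C G T U E` (plus `-` when `dash_as_E` is set).
#' The alphabet is taken from an `alphabet=DNA|RNA` tag in the description if
#' present, otherwise inferred (`U` implies RNA, default DNA); a
#' `direction=3to5` tag flips the direction label.  Explicit E letters become
#' explicit E entries; places run `1..L`.
#'
#' @param path FASTA file path.
#' @param dash_as_E Convert alignment gaps `-` to `E` on import.
#' @return A named list of `seqvec` objects.
#' @export
read_fasta <- function(path, dash_as_E = FALSE) {
  set <- Biostrings::readBStringSet(path)
  out <- vector("list", length(set))
  descs <- names(set)
  for (i in seq_along(set)) {
    out[[i]] <- parse_fasta_record(as.character(set[[i]]), descs[i], dash_as_E)
  }
  names(out) <- sub("[[:space:]].*$", "", descs)
  out
}

#' Write sequence vectors to FASTA
#'
#' @param seqs A `seqvec` or list of `seqvec`s.
#' @param path Output path.
#' @param mode `"conventional"` drops all E's and gaps; `"explicit"` writes E
#'   letters inline over the dense span `1..max(place)` (implicit gaps render
#'   as E).
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path, mode = c("conventional", "explicit")) {
  mode <- match.arg(mode)
  if (inherits(seqs, "seqvec")) seqs <- list(seqs)
  strings <- vapply(seqs, function(s) {
    if (mode == "conventional") {
      seq_text(s, "conventional")
    } else if (length(s$place) == 0L) {
      ""
    } else {
      full <- integer(max(s$place))
      full[s$place] <- s$index
      paste(base_letter(full, s$alphabet), collapse = "")
    }
  }, "")
  nms <- names(seqs)
  if (is.null(nms)) nms <- paste0("seq", seq_along(seqs))
  descs <- vapply(seq_along(seqs), function(i) {
    sprintf("%s alphabet=%s direction=%s", nms[i],
            seqs[[i]]$alphabet, seqs[[i]]$direction)
  }, "")
  set <- Biostrings::BStringSet(strings)
  names(set) <- descs
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write the evec JSON sidecar
#'
#' The evec format serialises a sequence vector with full place-number
#' bookkeeping:
#' `{"alphabet":"DNA","direction":"5to3","entries":[[1,"C"],[2,"T"],...]}`
#' with entries in ascending place order.  Serialisation is canonical, so
#' reading and re-writing a file is byte-exact.
#'
#' @param s A `seqvec`.
#' @param path File path.
#' @return `read_evec()` returns a `seqvec`; `write_evec()` returns the path,
#'   invisibly.
#' @export
write_evec <- function(s, path) {
  stopifnot(inherits(s, "seqvec"))
  entries <- lapply(seq_along(s$place), function(i) {
    list(s$place[i], base_letter(s$index[i], s$alphabet))
  })
  json <- jsonlite::toJSON(
    list(alphabet = s$alphabet, direction = s$direction, entries = entries),
    auto_unbox = TRUE
  )
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_evec
#' @export
read_evec <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$alphabet) || is.null(x$direction)) {
    stop("evec file missing alphabet/direction fields")
  }
  place <- vapply(x$entries, function(e) as.integer(e[[1]]), 1L)
  letters <- vapply(x$entries, function(e) as.character(e[[2]]), "")
  if (is.unsorted(place, strictly = TRUE)) {
    stop("evec entries must be in strictly ascending place order")
  }
  new_seqvec(place,
             if (length(letters)) base_index(letters, x$alphabet) else integer(),
             match.arg(x$alphabet, c("DNA", "RNA")),
             match.arg(x$direction, c("5to3", "3to5")))
}

#' Read and write the editlog JSON format
#'
#' Serialises an operator vector as
#' `{"entries":[[place,exponent],...],"alias":["r",...]}` with ascending
#' places and exponents in `1..4`; the alias field is a human-readable
#' redundancy and is ignored on read.
#'
#' @param B An `opvec`.
#' @param path File path.
#' @return `read_editlog()` returns an `opvec`; `write_editlog()` returns the
#'   path, invisibly.
#' @export
write_editlog <- function(B, path) {
  stopifnot(inherits(B, "opvec"))
  entries <- lapply(seq_along(B$place), function(i) {
    list(B$place[i], B$exponent[i])
  })
  json <- jsonlite::toJSON(
    list(entries = entries,
         alias = as.list(z5_alias(z5(B$exponent)))),
    auto_unbox = TRUE
  )
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_editlog
#' @export
read_editlog <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  place <- vapply(x$entries, function(e) as.integer(e[[1]]), 1L)
  expn <- vapply(x$entries, function(e) as.integer(e[[2]]), 1L)
  if (any(expn < 1L | expn > 4L)) stop("editlog exponents must lie in 1..4")
  new_opvec(place, expn)
}

#' Read an edit script from JSON
#'
#' Format: an array of steps, e.g.
#' `[{"op":"insertE","after":3,"count":2},
#'   {"op":"substitute","entries":[[1,3],[2,1]]},
#'   {"op":"deleteE","places":[4,5]}]`.
#'
#' @param path File path.
#' @return An [edit_script()].
#' @export
read_edit_script <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  steps <- lapply(x, function(st) {
    switch(st$op,
      insertE = edit_insertE(st$after, if (is.null(st$count)) 1L else st$count),
      deleteE = edit_deleteE(unlist(st$places)),
      substitute = edit_substitute(new_opvec(
        vapply(st$entries, function(e) as.integer(e[[1]]), 1L),
        vapply(st$entries, function(e) as.integer(e[[2]]), 1L)
      )),
      stop("unknown edit-script op: ", st$op)
    )
  })
  do.call(edit_script, steps)
}
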