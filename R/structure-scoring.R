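#' Split a sequence into overlapping windows
#'
#' Windows of `win` nt starting every `step` nt; the last window must fit
#' entirely (`start + win <= L`). Sequences shorter than `win` yield a single
#' full-length window.
#'
#' @param sequence a single character string (>= 1 nt).
#' @param win window length in nt (default 100).
#' @param step start-to-start offset in nt (default 50, i.e. 50-nt overlap).
#' @return data.frame with `start` (0-based), `end` (half-open) and `seq`.
#' @export
window_sequence <- function(sequence, win = 100, step = 50) {
  L <- nchar(sequence)
  if (L < 1) stop("empty sequence")
  starts <- if (L < win) 0L else seq(0L, L - win, by = step)
  ends <- pmin(starts + win, L)
  data.frame(start = starts, end = ends,
             seq = substring(sequence, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Built-in surrogate folding engine
#'
#' A Nussinov-style maximum base-pairing engine (minimum loop length
#' `min_loop`, GC/AU/GU pairs allowed, scored -1 per pair). The score is a
#' pseudo-energy in pair units, clearly non-thermodynamic, but ranks
#' structure-forming sequences similarly to a thermodynamic folder.
#'
#' @param min_loop minimum unpaired loop length (default 3).
#' @return list of class `"fold_engine"` with `name` and a vectorized
#'   `fold(sequences)` returning one score (<= 0) per sequence.
#' @export
builtin_fold_engine <- function(min_loop = 3) {
  structure(list(name = "nussinov",
                 fold = function(sequences)
                   nussinov_score(as.character(sequences), min_loop)),
            class = "fold_engine")
}

#' Thermodynamic folding engine via the RNAfold command-line tool
#'
#' Shells out to ViennaRNA's `RNAfold` and parses the minimum free energy in
#' kcal/mol. One process call folds all sequences.
#'
#' @param cmd path to the RNAfold executable.
#' @return a `"fold_engine"`.
#' @export
rnafold_engine <- function(cmd = "RNAfold") {
  if (Sys.which(cmd) == "") stop("RNAfold executable not found: ", cmd)
  structure(list(name = "RNAfold", fold = function(sequences) {
    sequences <- as.character(sequences)
    out <- system2(cmd, args = "--noPS", input = sequences, stdout = TRUE)
    hits <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
    if (length(hits) != length(sequences))
      stop("RNAfold returned ", length(hits), " energies for ",
           length(sequences), " sequences")
    as.numeric(gsub("[()\\s]", "", hits, perl = TRUE))
  }), class = "fold_engine")
}

#' @export
print.fold_engine <- function(x, ...) {
  cat(sprintf("fold_engine: %s\n", x$name))
  invisible(x)
}

#' Median windowed minimum folding energy of a sequence
#'
#' Divides the sequence into 100-nt windows with 50-nt overlap (see
#' [window_sequence()]), folds each window with the given engine, and
#' summarizes the sequence by the median window score. Windows on which the
#' engine fails are skipped with a warning; if all fail the result is `NA`.
#'
#' @param sequence character string.
#' @param engine a `"fold_engine"` (default [builtin_fold_engine()]).
#' @param win,step windowing parameters.
#' @return named list: `median_mfe`, `n_windows`, `window_mfe`.
#' @export
median_mfe <- function(sequence, engine = builtin_fold_engine(),
                       win = 100, step = 50) {
  w <- window_sequence(sequence, win, step)
  mfe <- tryCatch(engine$fold(w$seq), error = function(e) {
    vapply(w$seq, function(s)
      tryCatch(engine$fold(s), error = function(e2) NA_real_), numeric(1))
  })
  if (anyNA(mfe)) warning(sum(is.na(mfe)), " window(s) failed to fold; skipped")
  list(median_mfe = if (all(is.na(mfe))) NA_real_ else
         stats::median(mfe, na.rm = TRUE),
       n_windows = nrow(w), window_mfe = unname(mfe))
}

#' Gini index of a non-negative signal
#'
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`, in `[0, 1 - 1/n]`; higher
#' values mean the signal is concentrated on few positions (for
#' structure-probing reactivities, a proxy for structuredness). All-zero
#' input returns `NA`.
#'
#' @param values non-negative numeric vector.
#' @return the Gini index, or `NA`.
#' @export
gini <- function(values) {
  if (any(values < 0, na.rm = TRUE)) stop("values must be >= 0")
  x <- values[!is.na(values)]
  n <- length(x)
  if (!n || sum(x) == 0) return(NA_real_)
  x <- sort(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Median windowed Gini index of a per-position signal
#'
#' Applies the same 100-nt / 50-nt-overlap windowing as [median_mfe()] to a
#' per-position signal vector and reports the median per-window Gini index.
#'
#' @param signal non-negative numeric vector (one value per position).
#' @param win,step windowing parameters.
#' @return named list: `median_gini`, `n_windows`, `window_gini`.
#' @export
windowed_gini <- function(signal, win = 100, step = 50) {
  L <- length(signal)
  if (L < 1) stop("empty signal")
  starts <- if (L < win) 0L else seq(0L, L - win, by = step)
  g <- vapply(starts, function(s)
    gini(signal[(s + 1):min(s + win, L)]), numeric(1))
  list(median_gini = if (all(is.na(g))) NA_real_ else
         stats::median(g, na.rm = TRUE),
       n_windows = length(starts), window_gini = g)
}

#' Structure profile of a set of 3'UTR sequences
#'
#' Windowed-MFE scoring (and, where a probing signal is supplied, windowed
#' Gini indices) per region.
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet].
#' @param engine a `"fold_engine"`.
#' @param signal optional named list of per-position signal vectors (names
#'   matched to `sequences`).
#' @param win,step windowing parameters.
#' @return data.frame: `region_id`, `length`, `n_windows`, `median_mfe`,
#'   `median_gini`.
#' @export
structure_profile <- function(sequences, engine = builtin_fold_engine(),
                              signal = NULL, win = 100, step = 50) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  seqs <- as.character(sequences)
  rows <- lapply(seq_along(seqs), function(i) {
    m <- median_mfe(seqs[i], engine, win, step)
    g <- NA_real_
    if (!is.null(signal) && !is.null(signal[[ids[i]]]))
      g <- windowed_gini(signal[[ids[i]]], win, step)$median_gini
    data.frame(region_id = ids[i], length = nchar(seqs[i]),
               n_windows = m$n_windows, median_mfe = m$median_mfe,
               median_gini = g, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
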