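#' Construct an MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z (Th), positive.
#' @param fragments Two-column matrix or data.frame of fragment (mz,
#'   intensity); stored sorted by m/z.
#' @param rt Retention time in seconds (NA when unknown, e.g. public
#'   library entries).
#' @param mode Chromatography mode, "HILIC" or "RPLC".
#' @param polarity "pos" or "neg".
#' @param id Optional identifier (library entry name / feature id).
#' @return A `spectrum` object.
#' @export
spectrum <- function(precursor_mz, fragments, rt = NA_real_,
                     mode = c("HILIC", "RPLC"), polarity = "pos",
                     id = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(precursor_mz) || precursor_mz <= 0)
    stop("precursor_mz must be positive")
  fragments <- as.matrix(fragments)
  if (ncol(fragments) != 2L) stop("fragments must have columns (mz, intensity)")
  colnames(fragments) <- c("mz", "intensity")
  if (any(fragments[, "intensity"] < 0)) stop("negative fragment intensity")
  fragments <- fragments[order(fragments[, "mz"]), , drop = FALSE]
  structure(list(precursor_mz = precursor_mz, rt = rt, mode = mode,
                 polarity = polarity, fragments = fragments, id = id),
            class = "spectrum")
}

#' Spectral matching configuration
#'
#' Windows follow in-house library search practice: precursor and fragment
#' tolerance of 15 ppm, retention-time window of 30 s for HILIC and 20 s
#' for RPLC; matches are reported when the forward dot-product score is at
#' least `score_min`. Intensities are weighted by `intensity^intensity_power`
#' (square-root weighting by default, damping dominant peaks).
#'
#' @param precursor_ppm Precursor m/z tolerance (ppm).
#' @param rt_window_s Named vector of RT windows in seconds per mode.
#' @param fragment_ppm Fragment pairing tolerance (ppm).
#' @param score_min Minimum similarity score for a reported identification.
#' @param intensity_power Intensity weighting exponent.
#' @return A `match_config` list.
#' @export
match_config <- function(precursor_ppm = 15,
                         rt_window_s = c(HILIC = 30, RPLC = 20),
                         fragment_ppm = 15,
                         score_min = 0.4,
                         intensity_power = 0.5) {
  if (precursor_ppm <= 0 || fragment_ppm <= 0 || any(rt_window_s <= 0))
    stop("match_config: windows must be positive")
  if (score_min < 0 || score_min > 1)
    stop("match_config: score_min must be in [0, 1]")
  structure(list(precursor_ppm = precursor_ppm, rt_window_s = rt_window_s,
                 fragment_ppm = fragment_ppm, score_min = score_min,
                 intensity_power = intensity_power),
            class = c("match_config", "list"))
}

#' Find library candidates by precursor m/z and retention time
#'
#' Candidates satisfy |query mz - library mz| / library mz * 1e6 <=
#' `precursor_ppm` and, when the library entry carries a retention time
#' (in-house entries), |query RT - library RT| within the mode's window;
#' the RT filter is skipped for entries without RT (public libraries).
#'
#' @param query A [spectrum()].
#' @param library List of [spectrum()] library entries.
#' @param cfg A [match_config()].
#' @return Integer indices of candidate entries (empty when none).
#' @export
candidate_search <- function(query, library, cfg = match_config()) {
  if (length(library) == 0L) return(integer())
  keep <- vapply(library, function(entry) {
    ppm <- abs(query$precursor_mz - entry$precursor_mz) /
      entry$precursor_mz * 1e6
    if (ppm > cfg$precursor_ppm) return(FALSE)
    if (!is.na(entry$rt) && !is.na(query$rt)) {
      win <- cfg$rt_window_s[[query$mode]]
      if (abs(query$rt - entry$rt) > win) return(FALSE)
    }
    TRUE
  }, logical(1))
  which(keep)
}

# greedy one-to-one fragment pairing, closest m/z (in ppm) first
pair_fragments <- function(mz_q, mz_r, fragment_ppm) {
  cand <- list()
  for (i in seq_along(mz_q)) {
    ppm <- abs(mz_q[i] - mz_r) / mz_r * 1e6
    ok <- which(ppm <= fragment_ppm)
    for (j in ok)
      cand[[length(cand) + 1L]] <- c(i = i, j = j, ppm = ppm[j])
  }
  if (!length(cand)) return(matrix(integer(), ncol = 2L))
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "ppm"]), , drop = FALSE]
  used_q <- logical(length(mz_q)); used_r <- logical(length(mz_r))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (used_q[i] || used_r[j]) next
    used_q[i] <- TRUE; used_r[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  do.call(rbind, pairs)
}

#' Forward dot-product spectral similarity
#'
#' Fragments of query and reference are greedily paired one-to-one within
#' `fragment_ppm` (closest pairs first); with weights
#' w = intensity^intensity_power, the score is
#' (sum over pairs of w_q * w_r)^2 / (sum w_q^2 * sum w_r^2),
#' so unmatched fragments contribute only to the denominator and identical
#' spectra score exactly 1 (Cauchy-Schwarz).
#'
#' @param query,reference [spectrum()] objects with non-empty fragment
#'   lists.
#' @param cfg A [match_config()].
#' @return Score in [0, 1], plus attribute `n_matched`.
#' @export
forward_dot_product <- function(query, reference, cfg = match_config()) {
  fq <- query$fragments; fr <- reference$fragments
  if (nrow(fq) == 0L || nrow(fr) == 0L)
    stop("forward_dot_product: empty fragment list")
  wq <- fq[, "intensity"]^cfg$intensity_power
  wr <- fr[, "intensity"]^cfg$intensity_power
  pairs <- pair_fragments(fq[, "mz"], fr[, "mz"], cfg$fragment_ppm)
  num <- if (nrow(pairs)) sum(wq[pairs[, 1]] * wr[pairs[, 2]]) else 0
  score <- num^2 / (sum(wq^2) * sum(wr^2))
  structure(min(1, score), n_matched = nrow(pairs))
}

#' Annotate metabolic features against spectral libraries
#'
#' Per feature, the best forward dot-product score over all of its MS/MS
#' spectra and all precursor/RT candidates is taken, searching the in-house
#' library (standards with retention times) first and the public library
#' second. Confidence follows MSI levels: 1 for an in-house match (accurate
#' mass + RT + fragmentation), 2 for a public spectral match, 3 for a
#' caller-supplied putative assignment, 4 otherwise; matches scoring below
#' `score_min` are demoted to level 4 (no library id reported).
#'
#' @param feature_ids Character vector of feature ids to annotate.
#' @param spectra_map Named list mapping feature id to a list of query
#'   [spectrum()] objects (features may have none).
#' @param inhouse_library,public_library Lists of [spectrum()] entries
#'   (either may be empty).
#' @param cfg A [match_config()].
#' @param putative_ids Optional named character vector of putative names
#'   keyed by feature id (assigned MSI level 3 when no spectral match).
#' @return data.frame: feature_id, library_id, score, msi_level,
#'   n_matched_fragments.
#' @export
annotate_features <- function(feature_ids, spectra_map,
                              inhouse_library = list(),
                              public_library = list(),
                              cfg = match_config(),
                              putative_ids = NULL) {
  best_match <- function(spectra, library) {
    best <- list(score = -Inf, id = NA_character_, n = 0L)
    for (sp in spectra) {
      idx <- candidate_search(sp, library, cfg)
      for (i in idx) {
        s <- forward_dot_product(sp, library[[i]], cfg)
        if (s > best$score)
          best <- list(score = as.numeric(s),
                       id = library[[i]]$id %||% sprintf("entry_%d", i),
                       n = attr(s, "n_matched"))
      }
    }
    best
  }
  rows <- lapply(feature_ids, function(fid) {
    spectra <- spectra_map[[fid]]
    res <- data.frame(feature_id = fid, library_id = NA_character_,
                      score = NA_real_, msi_level = 4L,
                      n_matched_fragments = 0L, stringsAsFactors = FALSE)
    if (!is.null(spectra) && length(spectra)) {
      ih <- best_match(spectra, inhouse_library)
      if (is.finite(ih$score) && ih$score >= cfg$score_min) {
        res$library_id <- ih$id; res$score <- ih$score
        res$msi_level <- 1L; res$n_matched_fragments <- ih$n
        return(res)
      }
      pb <- best_match(spectra, public_library)
      if (is.finite(pb$score) && pb$score >= cfg$score_min) {
        res$library_id <- pb$id; res$score <- pb$score
        res$msi_level <- 2L; res$n_matched_fragments <- pb$n
        return(res)
      }
    }
    if (!is.null(putative_ids) && fid %in% names(putative_ids)) {
      res$library_id <- unname(putative_ids[[fid]])
      res$msi_level <- 3L
    }
    res
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read spectra from an MSP file
#'
#' Parses the NIST-style text format used by public spectral libraries:
#' blocks with `Name:`, `PrecursorMZ:` (or `PRECURSORMZ:`), optional
#' `RETENTIONTIME:` (seconds) and `Num Peaks:` followed by mz/intensity
#' pairs.
#'
#' @param path MSP file.
#' @param mode Chromatography mode tag applied to all entries.
#' @return List of [spectrum()] objects.
#' @export
read_msp <- function(path, mode = "HILIC") {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  get_field <- function(block, key) {
    hit <- grep(paste0("^", key, ":"), block, ignore.case = TRUE, value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^[^:]+:", "", hit[1]))
  }
  starts <- grep("^Name:", lines, ignore.case = TRUE)
  bounds <- c(starts, length(lines) + 1L)
  for (b in seq_along(starts)) {
    block <- lines[bounds[b]:(bounds[b + 1L] - 1L)]
    name <- get_field(block, "Name")
    pmz <- as.numeric(get_field(block, "PrecursorMZ"))
    rt <- suppressWarnings(as.numeric(get_field(block, "RETENTIONTIME")))
    npk_line <- grep("^Num ?Peaks:", block, ignore.case = TRUE)
    if (!length(npk_line) || is.na(pmz)) next
    npk <- as.integer(trimws(sub("^[^:]+:", "", block[npk_line[1]])))
    peak_lines <- block[seq(npk_line[1] + 1L, length.out = npk)]
    peaks <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t;]+"),
                                   function(x) as.numeric(x[1:2])))
    out[[length(out) + 1L]] <- spectrum(pmz, peaks, rt = rt, mode = mode,
                                        id = name)
  }
  out
}

#' Read spectra from an MGF file
#'
#' Parses BEGIN IONS / END IONS blocks with TITLE, PEPMASS and RTINSECONDS
#' headers.
#'
#' @inheritParams read_msp
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path, mode = "HILIC") {
  lines <- readLines(path)
  out <- list()
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  stopifnot(length(starts) == length(ends))
  for (b in seq_along(starts)) {
    block <- lines[(starts[b] + 1L):(ends[b] - 1L)]
    kv <- grepl("=", block, fixed = TRUE)
    fields <- strsplit(block[kv], "=", fixed = TRUE)
    keys <- toupper(vapply(fields, `[`, "", 1L))
    vals <- vapply(fields, function(x) paste(x[-1], collapse = "="), "")
    pmz <- as.numeric(strsplit(vals[match("PEPMASS", keys)], " ")[[1]][1])
    rt <- suppressWarnings(as.numeric(vals[match("RTINSECONDS", keys)]))
    title <- vals[match("TITLE", keys)]
    peaks <- do.call(rbind, lapply(strsplit(trimws(block[!kv]), "[ \t]+"),
                                   function(x) as.numeric(x[1:2])))
    out[[length(out) + 1L]] <- spectrum(pmz, peaks, rt = rt, mode = mode,
                                        id = if (is.na(title)) NULL else title)
  }
  out
}

#' Write spectra to an MSP file
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @export
write_msp <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c(sprintf("Name: %s", sp$id %||% "unknown"),
                 sprintf("PrecursorMZ: %.6f", sp$precursor_mz),
                 if (!is.na(sp$rt)) sprintf("RETENTIONTIME: %.2f", sp$rt),
                 sprintf("Num Peaks: %d", nrow(sp$fragments)),
                 sprintf("%.6f %.2f", sp$fragments[, "mz"],
                         sp$fragments[, "intensity"]),
                 ""), con)
  }
  invisible(path)
}
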