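# Domain scanning: six-frame translation and PSSM-based location of AP2 and
# B3 domains with completeness calls.

DNA_VALID <- strsplit("ACGTRYSWKMBDHVN", "")[[1]]

#' Translate a transcript in six frames
#'
#' Returns every stop-free peptide stretch of at least `min_orf_aa` residues
#' in all six reading frames. Coordinates are 0-based half-open on the
#' forward strand regardless of the candidate's strand. Ambiguous IUPAC
#' codes translate to "X".
#'
#' @param dna DNA sequence (character scalar).
#' @param min_orf_aa minimum peptide length.
#' @param id contig id carried into the result.
#' @return data.frame: contig, frame (0-2), strand ("+"/"-"), aa (peptide),
#'   nt_start, nt_end.
#' @export
six_frame_translate <- function(dna, min_orf_aa = 50L, id = "contig") {
  chars <- strsplit(toupper(dna), "")[[1]]
  bad <- which(!(chars %in% DNA_VALID))
  if (length(bad))
    stop("non-IUPAC DNA character '", chars[bad[1]], "' at offset ",
         bad[1] - 1L)
  out <- list()
  L <- length(chars)
  if (L == 0L)
    return(data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), aa = character(0),
                      nt_start = integer(0), nt_end = integer(0),
                      stringsAsFactors = FALSE))
  fwd <- Biostrings::DNAString(paste(chars, collapse = ""))
  rev <- Biostrings::reverseComplement(fwd)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd else rev
    for (f in 0:2) {
      len <- length(s) - f
      naa <- len %/% 3L
      if (naa < 1L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::subseq(s, start = f + 1L, width = naa * 3L),
        if.fuzzy.codon = "X"))
      runs <- stopfree_runs(aa, min_orf_aa)
      for (r in runs) {
        a1 <- r[1]; a2 <- r[2]
        if (strand == "+") {
          nt1 <- f + 3L * (a1 - 1L)
          nt2 <- f + 3L * a2
        } else {
          nt1 <- L - (f + 3L * a2)
          nt2 <- L - (f + 3L * (a1 - 1L))
        }
        out[[length(out) + 1L]] <- data.frame(
          contig = id, frame = f, strand = strand,
          aa = substr(aa, a1, a2), nt_start = nt1, nt_end = nt2,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), aa = character(0),
                      nt_start = integer(0), nt_end = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

stopfree_runs <- function(aa, min_len) {
  ch <- strsplit(aa, "")[[1]]
  stops <- c(0L, which(ch == "*"), length(ch) + 1L)
  runs <- list()
  for (k in seq_len(length(stops) - 1L)) {
    a1 <- stops[k] + 1L
    a2 <- stops[k + 1L] - 1L
    if (a2 - a1 + 1L >= min_len) runs[[length(runs) + 1L]] <- c(a1, a2)
  }
  runs
}

# Batched six-frame candidate extraction over a whole transcript set (one
# Biostrings translate call per strand/frame instead of six per sequence).
six_frame_candidates <- function(transcripts, min_orf_aa = 50L) {
  empty <- data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), aa = character(0),
                      nt_start = integer(0), nt_end = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(transcripts)) return(empty)
  set <- Biostrings::DNAStringSet(toupper(unlist(transcripts)))
  names(set) <- names(transcripts)
  rc <- Biostrings::reverseComplement(set)
  out <- list()
  for (strand in c("+", "-")) {
    s_all <- if (strand == "+") set else rc
    for (f in 0:2) {
      w <- Biostrings::width(s_all)
      naa <- pmax((w - f) %/% 3L, 0L)
      ok <- which(naa >= min_orf_aa)
      if (!length(ok)) next
      sub <- Biostrings::subseq(s_all[ok], start = f + 1L,
                                width = naa[ok] * 3L)
      aa_all <- as.character(Biostrings::translate(sub,
                                                   if.fuzzy.codon = "X"))
      for (k in seq_along(ok)) {
        id <- names(s_all)[ok[k]]
        L <- w[ok[k]]
        runs <- stopfree_runs(aa_all[k], min_orf_aa)
        for (r in runs) {
          a1 <- r[1]; a2 <- r[2]
          if (strand == "+") {
            nt1 <- f + 3L * (a1 - 1L); nt2 <- f + 3L * a2
          } else {
            nt1 <- L - (f + 3L * a2); nt2 <- L - (f + 3L * (a1 - 1L))
          }
          out[[length(out) + 1L]] <- data.frame(
            contig = id, frame = f, strand = strand,
            aa = substr(aa_all[k], a1, a2), nt_start = nt1, nt_end = nt2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Build a position-specific scoring model from a labelled alignment
#'
#' Log-odds against a uniform residue background with additive
#' pseudocounts. For a 59-column AP2 alignment, column 24 is the "167i"
#' insertion slot and is deletion-free (zero deletion penalty), so domains
#' without the group-IX insertion skip it at no cost.
#'
#' @param alignment character vector of equal-length aligned sequences
#'   (gaps as "-").
#' @param pseudocount additive pseudocount.
#' @param gap_open,gap_ext affine deletion/insertion penalties.
#' @param threshold acceptance fraction of the maximum attainable score over
#'   the matched span.
#' @param min_span minimum number of matched model columns for a hit.
#' @param insertion_col index of an optional insertion column, or NULL.
#' @param kind "AP2" or "B3".
#' @return object of class `position_model`.
#' @export
build_model <- function(alignment, pseudocount = 1, gap_open = 4,
                        gap_ext = 0.5, threshold = 0.6, min_span = 10L,
                        insertion_col = NULL, kind = "AP2") {
  if (length(alignment) < 2L) stop("need at least 2 aligned sequences")
  lens <- unique(nchar(alignment))
  if (length(lens) != 1L) stop("ragged alignment: unequal sequence lengths")
  C <- lens
  mat <- do.call(rbind, strsplit(alignment, ""))
  scores <- matrix(0, nrow = length(AA_ALPHABET), ncol = C,
                   dimnames = list(AA_ALPHABET, NULL))
  for (j in seq_len(C)) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    p <- (as.numeric(cnt) + pseudocount) /
      (length(col) + 20 * pseudocount)
    scores[, j] <- log2(p / 0.05)
  }
  del_open <- rep(gap_open, C)
  del_ext <- rep(gap_ext, C)
  core <- seq_len(C)
  if (!is.null(insertion_col)) {
    del_open[insertion_col] <- 0
    del_ext[insertion_col] <- 0
    core <- rep(NA_integer_, C)
    core[-insertion_col] <- seq_len(C - 1L)
  }
  structure(list(scores = scores, del_open = del_open, del_ext = del_ext,
                 ins_open = gap_open, ins_ext = gap_ext, core = core,
                 threshold = threshold, min_span = min_span, kind = kind),
            class = "position_model")
}

#' Default AP2 domain model
#'
#' Built deterministically from the per-group consensus domains (eleven ERF
#' groups plus the AP2- and RAV-family variants) over the 58 core positions
#' and the 167i insertion slot.
#'
#' @param threshold,min_span acceptance parameters, see [build_model()].
#' @return a `position_model` of 59 columns.
#' @export
ap2_model <- function(threshold = 0.6, min_span = 10L) {
  rows <- c(lapply(ERF_GROUPS, function(g)
    group_consensus("ERF", g, insertion_residue = "S")),
    list(group_consensus("AP2"), group_consensus("RAV")))
  aln <- vapply(rows, function(r) {
    r[is.na(r)] <- "-"
    paste(r, collapse = "")
  }, character(1))
  build_model(aln, insertion_col = match("167i", numbered_positions()),
              threshold = threshold, min_span = min_span, kind = "AP2")
}

#' Default B3 domain model (from the synthetic B3 consensus)
#'
#' @return a `position_model`.
#' @export
b3_model <- function() {
  build_model(c(B3_CONSENSUS, B3_CONSENSUS), threshold = 0.6,
              min_span = 30L, kind = "B3")
}

aa_codes <- function(aa) {
  codes <- match(strsplit(aa, "")[[1]], AA_ALPHABET)
  codes[is.na(codes)] <- 0L
  codes
}

# interpret an alignment path against a model into hit descriptors
path_to_hit <- function(path_i, path_j, score, model) {
  matched <- path_j > 0L & path_i > 0L
  core_cols <- model$core[path_j[matched]]
  core_cols <- core_cols[!is.na(core_cols)]
  if (!length(core_cols)) return(NULL)
  ms <- min(core_cols); me <- max(core_cols)
  deleted <- model$core[path_j[path_j > 0L & path_i == 0L]]
  deleted <- deleted[!is.na(deleted)]
  int_del <- sum(deleted > ms & deleted < me)
  has_ins <- any(is.na(model$core[path_j[matched]]))
  pep_idx <- path_i[path_i > 0L]
  model_len <- max(model$core, na.rm = TRUE)
  list(pep_start = min(pep_idx) - 1L, pep_end = max(pep_idx),
       model_start = ms, model_end = me, score = score,
       n_internal_del = int_del, has_insertion = has_ins,
       completeness = completeness_call(ms, me, int_del, model_len))
}

# Local alignment trims weakly scoring (noise-substituted) terminal model
# columns. When a trimmed end is within `max_ext` columns of the model
# boundary and the peptide has adjacent residues to cover them, extend the
# matched span gaplessly column by column; the refinement is kept only if
# the extended hit still clears the score threshold over its span.
extend_hit <- function(h, codes, model, max_ext = 6L) {
  model_len <- max(model$core, na.rm = TRUE)
  miss_n <- h$model_start - 1L
  miss_c <- model_len - h$model_end
  if ((miss_n == 0L || miss_n > max_ext) &&
      (miss_c == 0L || miss_c > max_ext)) return(h)
  h2 <- h
  col_of <- function(core) which(model$core == core)
  if (miss_n <= max_ext) {
    while (h2$model_start > 1L && h2$pep_start > 0L) {
      code <- codes[h2$pep_start]
      if (code == 0L) break
      j <- col_of(h2$model_start - 1L)
      h2$score <- h2$score + model$scores[code, j]
      h2$pep_start <- h2$pep_start - 1L
      h2$model_start <- h2$model_start - 1L
    }
  }
  if (miss_c <= max_ext) {
    while (h2$model_end < model_len && h2$pep_end < length(codes)) {
      code <- codes[h2$pep_end + 1L]
      if (code == 0L) break
      j <- col_of(h2$model_end + 1L)
      h2$score <- h2$score + model$scores[code, j]
      h2$pep_end <- h2$pep_end + 1L
      h2$model_end <- h2$model_end + 1L
    }
  }
  if (identical(h2, h)) return(h)
  if (h2$score < model$threshold * span_max_score(model, h2$model_start,
                                                  h2$model_end))
    return(h)
  h2$completeness <- completeness_call(h2$model_start, h2$model_end,
                                       h2$n_internal_del, model_len)
  h2
}

completeness_call <- function(ms, me, int_del, model_len) {
  if (ms == 1L && me == model_len) {
    if (int_del >= 4L) "short" else "full"
  } else if (ms > 1L && me == model_len) "partial_N"
  else if (ms == 1L && me < model_len) "partial_C"
  else "partial_both"
}

# maximum attainable score over core columns ms..me
span_max_score <- function(model, ms, me) {
  cols <- which(!is.na(model$core) & model$core >= ms & model$core <= me)
  sum(apply(model$scores[, cols, drop = FALSE], 2, max))
}

#' Scan a peptide for AP2 domains
#'
#' Greedy best-score-first local alignment against the model; accepted hits
#' (score at least the threshold fraction of the maximum attainable score
#' over the matched model span, span at least `min_span` columns) are masked
#' and the scan repeats, so up to `max_hits` non-overlapping domains are
#' reported per peptide.
#'
#' @param aa peptide sequence (character scalar).
#' @param model a `position_model` from [ap2_model()] or [build_model()].
#' @param max_hits maximum domains per peptide.
#' @return data.frame of hits: kind, pep_start, pep_end (0-based half-open,
#'   amino-acid coordinates), model_start, model_end, score, completeness,
#'   has_insertion, n_internal_del.
#' @export
scan_ap2 <- function(aa, model = ap2_model(), max_hits = 4L) {
  codes <- aa_codes(aa)
  hits <- list()
  while (length(hits) < max_hits) {
    al <- profile_align_cpp(codes, model$scores, model$del_open,
                            model$del_ext, model$ins_open, model$ins_ext, 0L)
    if (!length(al$path_i)) break
    h <- path_to_hit(al$path_i, al$path_j, al$score, model)
    if (is.null(h)) break
    span <- h$model_end - h$model_start + 1L
    if (span < model$min_span ||
        h$score < model$threshold * span_max_score(model, h$model_start,
                                                   h$model_end)) break
    h <- extend_hit(h, codes, model)
    h$kind <- model$kind
    hits[[length(hits) + 1L]] <- h
    codes[(h$pep_start + 1L):h$pep_end] <- 0L
  }
  if (!length(hits))
    return(data.frame(kind = character(0), pep_start = integer(0),
                      pep_end = integer(0), model_start = integer(0),
                      model_end = integer(0), score = numeric(0),
                      completeness = character(0), has_insertion = logical(0),
                      n_internal_del = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, lapply(hits, function(h)
    data.frame(kind = h$kind, pep_start = h$pep_start, pep_end = h$pep_end,
               model_start = h$model_start, model_end = h$model_end,
               score = h$score, completeness = h$completeness,
               has_insertion = h$has_insertion,
               n_internal_del = h$n_internal_del, stringsAsFactors = FALSE)))
}

#' Scan a peptide for B3 domains
#'
#' Same mechanics as [scan_ap2()] with the B3 model.
#'
#' @inheritParams scan_ap2
#' @export
detect_b3 <- function(aa, model = b3_model(), max_hits = 2L) {
  scan_ap2(aa, model, max_hits)
}

#' Scan a set of transcripts for AP2 and B3 domains
#'
#' Six-frame translation followed by domain scans on every candidate
#' peptide; hits from different frames of one contig that overlap on the
#' forward strand are reconciled best-score-first.
#'
#' @param transcripts named character vector of DNA sequences.
#' @param ap2,b3 position models.
#' @param min_orf_aa minimum peptide candidate length.
#' @return data.frame of hits with columns contig, frame, strand, kind,
#'   nt_start, nt_end (forward strand, 0-based half-open), pep_start,
#'   pep_end, model_start, model_end, score, completeness, has_insertion,
#'   n_internal_del, aa (the matched peptide substring).
#' @export
scan_transcripts <- function(transcripts, ap2 = ap2_model(),
                             b3 = b3_model(), min_orf_aa = 50L) {
  all_cands <- six_frame_candidates(transcripts, min_orf_aa)
  all_hits <- list()
  for (id in names(transcripts)) {
    cands <- all_cands[all_cands$contig == id, , drop = FALSE]
    for (ci in seq_len(nrow(cands))) {
      cand <- cands[ci, ]
      for (model in list(ap2, b3)) {
        hs <- scan_ap2(cand$aa, model)
        if (!nrow(hs)) next
        hs$contig <- cand$contig
        hs$frame <- cand$frame
        hs$strand <- cand$strand
        hs$aa <- substr(cand$aa, hs$pep_start + 1L, hs$pep_end)
        if (cand$strand == "+") {
          hs$nt_start <- cand$nt_start + 3L * hs$pep_start
          hs$nt_end <- cand$nt_start + 3L * hs$pep_end
        } else {
          hs$nt_end <- cand$nt_end - 3L * hs$pep_start
          hs$nt_start <- cand$nt_end - 3L * hs$pep_end
        }
        all_hits[[length(all_hits) + 1L]] <- hs
      }
    }
  }
  if (!length(all_hits))
    return(data.frame(contig = character(0), frame = integer(0),
                      strand = character(0), kind = character(0),
                      nt_start = integer(0), nt_end = integer(0),
                      pep_start = integer(0), pep_end = integer(0),
                      model_start = integer(0), model_end = integer(0),
                      score = numeric(0), completeness = character(0),
                      has_insertion = logical(0), n_internal_del = integer(0),
                      aa = character(0), stringsAsFactors = FALSE))
  hits <- do.call(rbind, all_hits)
  # reconcile overlapping hits (same contig, same kind) across frames
  keep <- rep(TRUE, nrow(hits))
  ord <- order(hits$contig, hits$kind, -hits$score)
  for (grp in split(ord, paste(hits$contig[ord], hits$kind[ord]))) {
    taken <- list()
    for (i in grp) {
      ov <- any(vapply(taken, function(iv)
        hits$nt_start[i] < iv[2] && iv[1] < hits$nt_end[i], logical(1)))
      if (ov) keep[i] <- FALSE
      else taken[[length(taken) + 1L]] <- c(hits$nt_start[i], hits$nt_end[i])
    }
  }
  hits <- hits[keep, , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("contig", "frame", "strand", "kind", "nt_start", "nt_end",
           "pep_start", "pep_end", "model_start", "model_end", "score",
           "completeness", "has_insertion", "n_internal_del", "aa")]
}
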