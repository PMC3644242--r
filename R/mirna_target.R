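# Plant miRNA target prediction: penalty-scored window alignment with
# protected positions, per-pair duplex energy, inhibition-mode call and
# site region annotation.

#' Target-scan parameters
#'
#' Defaults are the published custom parameters: gap 2, mismatch 1, G:U
#' wobble 0.5, penalty threshold 3, minimum alignment length 15, protected
#' miRNA positions 10-11, duplex energy cutoff -20 kcal/mol.
#'
#' @param gap,mismatch,gu additive penalties.
#' @param threshold maximum accepted total penalty.
#' @param min_length minimum alignment length (columns).
#' @param protected miRNA positions (1-based from the 5' end) that must be
#'   paired (Watson-Crick or wobble).
#' @param energy_cutoff maximum duplex free energy (kcal/mol).
#' @return list of class `target_scan_params`.
#' @export
target_scan_params <- function(gap = 2, mismatch = 1, gu = 0.5,
                               threshold = 3, min_length = 15L,
                               protected = c(10L, 11L),
                               energy_cutoff = -20) {
  if (any(c(gap, mismatch, gu) < 0)) stop("penalties must be >= 0")
  if (threshold <= 0) stop("threshold must be > 0")
  structure(list(gap = gap, mismatch = mismatch, gu = gu,
                 threshold = threshold, min_length = as.integer(min_length),
                 protected = as.integer(protected),
                 energy_cutoff = energy_cutoff),
            class = "target_scan_params")
}

# Per-pair duplex energy model (kcal/mol); an overridable package constant.
DUPLEX_ENERGY_TABLE <- c(GC = -3, AU = -2, GU = -1)

as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

pair_class <- function(q, t) {
  # q, t: single bases in RNA alphabet
  if (q == "-" || t == "-") return("gap")
  wc <- (q == "A" && t == "U") || (q == "U" && t == "A") ||
    (q == "G" && t == "C") || (q == "C" && t == "G")
  if (wc) return("wc")
  if ((q == "G" && t == "U") || (q == "U" && t == "G")) return("wobble")
  "mismatch"
}

#' Per-pair duplex free energy of an aligned miRNA:target pair
#'
#' Both fragments are given 5'->3' (as printed); they are paired
#' antiparallel (column k of the miRNA against column n-k+1 of the target).
#' The additive per-pair model scores G:C -3.0, A:U -2.0, G:U -1.0 and
#' non-pairs/gaps 0 kcal/mol.
#'
#' @param mir_fragment,target_fragment equal-length gapped strings
#'   (RNA or DNA alphabet).
#' @param table per-pair energy table (named: GC, AU, GU).
#' @return free energy in kcal/mol.
#' @export
duplex_energy <- function(mir_fragment, target_fragment,
                          table = DUPLEX_ENERGY_TABLE) {
  q <- strsplit(as_rna(mir_fragment), "")[[1]]
  t <- rev(strsplit(as_rna(target_fragment), "")[[1]])
  if (length(q) != length(t))
    stop("aligned fragments must have equal length")
  e <- 0
  for (k in seq_along(q)) {
    cls <- pair_class(q[k], t[k])
    e <- e + switch(cls,
                    wc = if (q[k] %in% c("G", "C")) table[["GC"]]
                         else table[["AU"]],
                    wobble = table[["GU"]],
                    0)
  }
  e
}

#' Scan a transcript for miRNA binding sites
#'
#' Aligns the miRNA against every transcript window (gaps allowed), scoring
#' additive penalties per miRNA position from its 5' end (gap `gap`,
#' non-pair `mismatch`, G:U wobble `gu`). Hits are kept when the total
#' penalty is at most `threshold`, the alignment spans at least
#' `min_length` columns, the protected positions are paired (Watson-Crick
#' or wobble) and the per-pair duplex energy is at most `energy_cutoff`.
#' Overlapping hits resolve to the lowest penalty.
#'
#' @param mirna miRNA sequence, 5'->3' (15-30 nt, RNA or DNA alphabet).
#' @param transcript target DNA/RNA sequence.
#' @param params a [target_scan_params()].
#' @param mirna_id,transcript_id labels carried into the result.
#' @return data.frame (MiRHit): mirna_id, contig, tx_start, tx_end (0-based
#'   half-open), penalty, energy, length, mir_fragment, target_fragment
#'   (both 5'->3'), inhibition.
#' @export
scan_targets <- function(mirna, transcript, params = target_scan_params(),
                         mirna_id = "miRNA", transcript_id = "contig") {
  mir <- as_rna(mirna)
  tx <- as_rna(transcript)
  if (grepl("[^ACGU]", mir) || grepl("[^ACGU]", tx))
    stop("non-RNA/DNA characters in input sequences")
  m <- nchar(mir)
  if (m < 15L || m > 30L) stop("miRNA length must be 15-30 nt")
  L <- nchar(tx)
  empty <- data.frame(mirna_id = character(0), contig = character(0),
                      tx_start = integer(0), tx_end = integer(0),
                      penalty = numeric(0), energy = numeric(0),
                      length = integer(0), mir_fragment = character(0),
                      target_fragment = character(0),
                      inhibition = character(0), stringsAsFactors = FALSE)
  if (L < params$min_length) return(empty)

  # reversed miRNA faces the transcript left-to-right (antiparallel duplex)
  R <- rev(strsplit(mir, "")[[1]])
  t_chars <- strsplit(tx, "")[[1]]

  # penalty of R[i] opposite each transcript base, vectorised
  pen_row <- function(i) {
    q <- R[i]
    wc_partner <- switch(q, A = "U", U = "A", G = "C", C = "G")
    p <- rep(params$mismatch, L)
    p[t_chars == wc_partner] <- 0
    if (q == "G") p[t_chars == "U"] <- params$gu
    if (q == "U") p[t_chars == "G"] <- params$gu
    p
  }

  gap <- params$gap
  idx <- seq_len(L)
  Dprev <- rep(0, L + 1L)                       # row 0: free start anywhere
  for (i in seq_len(m)) {
    pen <- pen_row(i)
    tmp <- pmin(Dprev[idx] + pen,               # diagonal
                Dprev[idx + 1L] + gap)          # miRNA base unopposed
    d0 <- Dprev[1L] + gap                       # column 0: leading overhang
    cm <- cummin(c(d0, tmp - gap * idx))
    Dprev <- c(d0, cm[-1L] + gap * idx)
  }
  cand_end <- which(Dprev[-1L] <= params$threshold + 1e-9)
  if (!length(cand_end)) return(empty)

  hits <- list()
  for (j in cand_end) {
    tb <- mir_traceback(R, t_chars, j, params)
    if (is.null(tb)) next
    hits[[length(hits) + 1L]] <- tb
  }
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  # resolve overlaps: lowest penalty, then leftmost, then lowest energy
  hits <- hits[order(hits$penalty, hits$tx_start, hits$energy), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  taken <- list()
  for (k in seq_len(nrow(hits))) {
    ov <- any(vapply(taken, function(iv)
      hits$tx_start[k] < iv[2] && iv[1] < hits$tx_end[k], logical(1)))
    if (ov) keep[k] <- FALSE
    else taken[[length(taken) + 1L]] <- c(hits$tx_start[k], hits$tx_end[k])
  }
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits$mirna_id <- mirna_id
  hits$contig <- transcript_id
  rownames(hits) <- NULL
  hits[, c("mirna_id", "contig", "tx_start", "tx_end", "penalty", "energy",
           "length", "mir_fragment", "target_fragment", "inhibition")]
}

# small windowed DP with traceback for one candidate end position
mir_traceback <- function(R, t_chars, j_end, params) {
  m <- length(R)
  w0 <- max(0L, j_end - m - 3L)                 # window start (0-based)
  W <- j_end - w0
  tw <- t_chars[(w0 + 1L):j_end]
  gap <- params$gap
  D <- matrix(Inf, m + 1L, W + 1L)
  P <- matrix(0L, m + 1L, W + 1L)               # 1 diag, 2 up, 3 left
  D[1L, ] <- 0
  for (i in seq_len(m)) D[i + 1L, 1L] <- i * gap
  P[-1L, 1L] <- 2L
  for (i in seq_len(m)) {
    for (j in seq_len(W)) {
      cls <- pair_class(R[i], tw[j])
      pen <- switch(cls, wc = 0, wobble = params$gu, params$mismatch)
      cand <- c(D[i, j] + pen, D[i, j + 1L] + gap, D[i + 1L, j] + gap)
      b <- which.min(cand)
      D[i + 1L, j + 1L] <- cand[b]
      P[i + 1L, j + 1L] <- b
    }
  }
  penalty <- D[m + 1L, W + 1L]
  if (penalty > params$threshold + 1e-9) return(NULL)
  # traceback
  i <- m; j <- W
  q_frag <- character(0); t_frag <- character(0); classes <- character(0)
  mir_pos <- integer(0)                         # miRNA 5'-based position
  while (i > 0L) {
    op <- P[i + 1L, j + 1L]
    if (op == 1L) {
      q_frag <- c(R[i], q_frag); t_frag <- c(tw[j], t_frag)
      classes <- c(pair_class(R[i], tw[j]), classes)
      mir_pos <- c(m - i + 1L, mir_pos)
      i <- i - 1L; j <- j - 1L
    } else if (op == 2L) {
      q_frag <- c(R[i], q_frag); t_frag <- c("-", t_frag)
      classes <- c("gap", classes)
      mir_pos <- c(m - i + 1L, mir_pos)
      i <- i - 1L
    } else {
      q_frag <- c("-", q_frag); t_frag <- c(tw[j], t_frag)
      classes <- c("gap", classes)
      mir_pos <- c(NA_integer_, mir_pos)
      j <- j - 1L
    }
  }
  len <- length(classes)
  if (len < params$min_length) return(NULL)
  prot_cls <- classes[match(params$protected, mir_pos)]
  if (any(is.na(prot_cls)) || any(!(prot_cls %in% c("wc", "wobble"))))
    return(NULL)
  tx_start <- w0 + j                            # 0-based
  tx_end <- j_end
  # fragments: transcript window left-to-right is 5'->3'; the facing
  # miRNA run is 3'->5', so reverse it for the printed 5'->3' form
  mir_fragment <- paste(rev(q_frag), collapse = "")
  target_fragment <- paste(t_frag, collapse = "")
  energy <- duplex_energy(mir_fragment, target_fragment)
  if (energy > params$energy_cutoff + 1e-9) return(NULL)
  inhibition <- if (all(classes[match(9:11, mir_pos)] %in% "wc"))
    "cleavage" else "translation"
  data.frame(tx_start = tx_start, tx_end = tx_end, penalty = penalty,
             energy = energy, length = len, mir_fragment = mir_fragment,
             target_fragment = target_fragment, inhibition = inhibition,
             stringsAsFactors = FALSE)
}

#' Inhibition-mode call for an accepted hit
#'
#' Cleavage when miRNA positions 9-11 are all Watson-Crick paired;
#' translation inhibition otherwise (a wobble at a central position is not
#' Watson-Crick).
#'
#' @param hit one row of [scan_targets()] output (uses the aligned
#'   fragments).
#' @return "cleavage" or "translation".
#' @export
call_inhibition <- function(hit) {
  q <- rev(strsplit(as_rna(hit$mir_fragment), "")[[1]])  # 3'->5'
  t <- strsplit(as_rna(hit$target_fragment), "")[[1]]
  m <- sum(q != "-")
  pos_counter <- cumsum(q != "-")               # position from miRNA 3' end
  cls <- vapply(seq_along(q), function(k) pair_class(q[k], t[k]),
                character(1))
  central <- vapply(9:11, function(p) {
    k <- which(q != "-" & (m - pos_counter + 1L) == p)
    if (!length(k)) return("gap")
    cls[k]
  }, character(1))
  if (all(central == "wc")) "cleavage" else "translation"
}

#' Annotate a site's position relative to CDS and AP2 domain
#'
#' The region containing the site midpoint decides the label.
#'
#' @param site_start,site_end site interval (0-based half-open, transcript
#'   coordinates).
#' @param cds CDS interval `c(start, end)` or NULL.
#' @param ap2 AP2-domain nucleotide interval `c(start, end)` or NULL.
#' @param tx_len transcript length.
#' @return one of "5'UTR", "CDS-before-AP2", "CDS-inside-AP2",
#'   "CDS-after-AP2", "3'UTR" (or "CDS"/"unknown" when intervals are
#'   absent).
#' @export
annotate_site <- function(site_start, site_end, cds = NULL, ap2 = NULL,
                          tx_len = Inf) {
  if (site_start < 0 || site_end > tx_len || site_start >= site_end)
    stop("site interval outside transcript")
  mid <- (site_start + site_end - 1L) %/% 2L
  if (is.null(cds)) return("unknown")
  if (mid < cds[1]) return("5'UTR")
  if (mid >= cds[2]) return("3'UTR")
  if (is.null(ap2)) return("CDS")
  if (mid < ap2[1]) "CDS-before-AP2"
  else if (mid < ap2[2]) "CDS-inside-AP2"
  else "CDS-after-AP2"
}

#' Scan a miRNA set against a transcript set
#'
#' @param mirnas named character vector of miRNA sequences.
#' @param transcripts named character vector of transcripts.
#' @param params a [target_scan_params()].
#' @param annotations optional data.frame (gene, cds_start, cds_end,
#'   ap2_start, ap2_end) for region labels.
#' @return combined hit data.frame with a `region` column when annotations
#'   are given.
#' @export
scan_target_set <- function(mirnas, transcripts,
                            params = target_scan_params(),
                            annotations = NULL) {
  out <- list()
  for (mid in names(mirnas)) {
    for (tid in names(transcripts)) {
      h <- scan_targets(mirnas[[mid]], transcripts[[tid]], params,
                        mirna_id = mid, transcript_id = tid)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(mirna_id = character(0), contig = character(0),
                      tx_start = integer(0), tx_end = integer(0),
                      penalty = numeric(0), energy = numeric(0),
                      length = integer(0), mir_fragment = character(0),
                      target_fragment = character(0),
                      inhibition = character(0), region = character(0),
                      stringsAsFactors = FALSE))
  hits <- do.call(rbind, out)
  if (!is.null(annotations)) {
    hits$region <- vapply(seq_len(nrow(hits)), function(k) {
      a <- annotations[annotations$gene == hits$contig[k], , drop = FALSE]
      if (!nrow(a)) return("unknown")
      cds <- if (is.na(a$cds_start[1])) NULL else c(a$cds_start[1],
                                                    a$cds_end[1])
      ap2 <- if (is.na(a$ap2_start[1])) NULL else c(a$ap2_start[1],
                                                    a$ap2_end[1])
      annotate_site(hits$tx_start[k], hits$tx_end[k], cds, ap2,
                    tx_len = nchar(transcripts[[hits$contig[k]]]))
    }, character(1))
  }
  rownames(hits) <- NULL
  hits
}
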