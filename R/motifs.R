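DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix from counts or probabilities
#'
#' @param mat width x 4 numeric matrix (columns A, C, G, T) of counts or
#'   probabilities.
#' @param motif_id Motif identifier.
#' @param tf_name Associated transcription-factor name (optional).
#' @param pseudocount Added to every cell before row-normalising counts
#'   (default 0.1). Rows already summing to 1 (within 1e-4, allowing for
#'   file rounding) are taken as probabilities and renormalised exactly.
#' @param background Named background base frequencies (default uniform).
#' @return Object of class `pwm`: `motif_id`, `tf_name`, `width`, `probs`,
#'   `background`, `pseudocount`.
#' @export
pwm <- function(mat, motif_id, tf_name = NA_character_, pseudocount = 0.1,
                background = NULL) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 4, nrow(mat) >= 1, all(mat >= 0))
  colnames(mat) <- DNA_BASES
  rs <- rowSums(mat)
  if (any(rs <= 0)) stop("motif ", motif_id, ": row with non-positive total")
  if (all(abs(rs - 1) < 1e-4)) {
    mat <- mat / rs  # already probabilities (up to file rounding)
  } else {
    mat <- (mat + pseudocount) / (rs + 4 * pseudocount)
  }
  if (is.null(background)) background <- rep(0.25, 4)
  background <- setNames(as.numeric(background), DNA_BASES)
  stopifnot(abs(sum(background) - 1) < 1e-6)
  structure(list(motif_id = motif_id, tf_name = tf_name,
                 width = nrow(mat), probs = mat,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM %s (%s), width %d, consensus %s\n", x$motif_id,
              x$tf_name, x$width, pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (most probable base per position)
#' @param x A `pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(DNA_BASES[apply(x$probs, 1, which.max)], collapse = "")
}

#' Reverse-complement a PWM
#' @param x A `pwm`.
#' @return A `pwm` scoring the reverse strand.
#' @export
pwm_revcomp <- function(x) {
  rc <- x$probs[rev(seq_len(x$width)), rev(seq_len(4)), drop = FALSE]
  colnames(rc) <- DNA_BASES
  out <- x
  out$probs <- rc
  out$background <- setNames(x$background[rev(seq_len(4))], DNA_BASES)
  out
}

#' Read motifs from MEME-minimal or JASPAR PFM text
#'
#' JASPAR PFMs (count matrices) are converted to probabilities with the
#' pseudocount; MEME-minimal files already carry probabilities, and their
#' background line is honoured when present. Motifs with a zero-total row
#' are rejected with a message naming the motif.
#'
#' @param path Motif file.
#' @param format `"auto"` (default, sniffed from content), `"meme"` or
#'   `"jaspar"`.
#' @param pseudocount For count matrices (default 0.1).
#' @return List of `pwm` objects, named by motif id.
#' @export
read_motifs <- function(path, format = c("auto", "meme", "jaspar"),
                        pseudocount = 0.1) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "auto") {
    format <- if (any(grepl("^MEME version", lines))) "meme" else "jaspar"
  }
  if (format == "meme") read_meme(lines, pseudocount)
  else read_jaspar(lines, pseudocount)
}

read_meme <- function(lines, pseudocount) {
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i) == 1 && bg_i < length(lines)) {
    tok <- strsplit(trimws(lines[bg_i + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok[c(FALSE, TRUE)]))
    if (length(vals) == 4 && !anyNA(vals)) bg <- vals
  }
  starts <- grep("^MOTIF", lines)
  out <- list()
  for (s in starts) {
    tok <- strsplit(trimws(lines[s]), "\\s+")[[1]]
    id <- tok[2]
    tf <- if (length(tok) >= 3) tok[3] else NA_character_
    hdr <- grep("^letter-probability matrix", lines[s:length(lines)])[1] + s - 1
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- do.call(rbind, lapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])))
    res <- tryCatch(pwm(mat, id, tf, pseudocount, bg),
                    error = function(e) {
                      message("motif rejected: ", conditionMessage(e)); NULL
                    })
    if (!is.null(res)) out[[id]] <- res
  }
  out
}

read_jaspar <- function(lines, pseudocount) {
  hdr <- grep("^>", lines)
  out <- list()
  for (i in seq_along(hdr)) {
    tok <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    id <- tok[1]
    tf <- if (length(tok) >= 2) tok[2] else NA_character_
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    block <- lines[(hdr[i] + 1):to]
    block <- block[nzchar(trimws(block))][1:4]
    rows <- lapply(block, function(r) {
      r <- gsub("^[ACGT]\\s*\\[|\\]", "", trimws(r))
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    mat <- t(do.call(rbind, rows))  # JASPAR rows are bases, columns positions
    res <- tryCatch(pwm(mat, id, tf, pseudocount),
                    error = function(e) {
                      message("motif rejected: ", conditionMessage(e)); NULL
                    })
    if (!is.null(res)) out[[id]] <- res
  }
  out
}

#' Write motifs in MEME-minimal format
#' @param motifs List of `pwm` objects.
#' @param path Output path.
#' @param background Background frequencies written to the header.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "", "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$motif_id,
                       ifelse(is.na(m$tf_name), m$motif_id, m$tf_name)), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$width),
      con)
    for (j in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", m$probs[j, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

# Discretized log-odds representation and exact null distribution.
# Per-position log2-odds scores are rounded onto a grid whose bin width is
# 1/granularity of the widest per-position score range; the null
# distribution of the integer total score under the background is then an
# exact convolution, giving tail p-values accurate to the discretization.
pwm_score_table <- function(pwm, background = NULL, granularity = 1000L) {
  bg <- if (is.null(background)) pwm$background else
    setNames(as.numeric(background), DNA_BASES)
  S <- log2(sweep(pwm$probs, 2, bg, "/"))
  rng <- apply(S, 1, function(r) diff(range(r)))
  bin <- max(rng) / granularity
  if (bin == 0) bin <- 1  # uninformative motif: all scores identical
  mins <- apply(S, 1, min)
  K <- round(sweep(S, 1, mins, "-") / bin)
  storage.mode(K) <- "integer"
  # null distribution of sum(K) by convolution over positions
  pv <- 1
  for (j in seq_len(pwm$width)) {
    nxt <- numeric(length(pv) + max(K[j, ]))
    for (b in 1:4) {
      k <- K[j, b]
      nxt[(1:length(pv)) + k] <- nxt[(1:length(pv)) + k] + pv * bg[b]
    }
    pv <- nxt
  }
  tail_p <- rev(cumsum(rev(pv)))
  tail_p <- pmin(tail_p, 1)
  list(S = S, K = K, bin = bin, offset = sum(mins), tail_p = tail_p, bg = bg)
}

scan_one_strand <- function(codes, masked, tab, width, p_threshold) {
  L <- length(codes)
  if (width > L) return(NULL)
  n_win <- L - width + 1L
  ints <- rep(0L, n_win)
  real <- rep(0, n_win)
  bad <- rep(FALSE, n_win)
  for (j in seq_len(width)) {
    idx <- codes[j:(j + n_win - 1L)]
    mj <- masked[j:(j + n_win - 1L)]
    nas <- is.na(idx)
    bad <- bad | nas | mj
    idx[nas] <- 1L
    ints <- ints + tab$K[j, idx]
    real <- real + tab$S[j, idx]
  }
  p <- tab$tail_p[ints + 1L]
  hit <- !bad & p < p_threshold
  if (!any(hit)) return(NULL)
  data.frame(offset = which(hit) - 1L, score = real[hit], p = p[hit])
}

#' Scan a sequence with a PWM, FIMO-style
#'
#' Both strands are scored with the summed log2 likelihood ratio of motif
#' over background; the p-value of each window is the exact probability of
#' an equal-or-better score under the background model, computed by
#' dynamic-programming convolution of the discretized per-position score
#' distribution. Hits with `p < p_threshold` are reported.
#'
#' Windows containing `N` are never scored; with `mask = "skip"` (the
#' default) windows touching lowercase (repeat-masked) bases are skipped
#' too.
#'
#' @param seq A DNA string (character scalar or `DNAString`); lowercase
#'   indicates repeat masking.
#' @param pwm A `pwm` object.
#' @param p_threshold Report hits below this p-value (default 1e-4).
#' @param background Optional background base frequencies; defaults to the
#'   motif's own.
#' @param mask `"skip"` (honour lowercase masking) or `"ignore"`.
#' @param granularity Discretization bins per position (default 1000).
#' @return data.frame of hits: `motif_id`, `offset` (0-based, on the
#'   forward strand), `strand`, `score` (log2 odds), `p`; sorted by
#'   position then strand.
#' @export
scan_pwm <- function(seq, pwm, p_threshold = 1e-4, background = NULL,
                     mask = c("skip", "ignore"), granularity = 1000L) {
  mask <- match.arg(mask)
  s <- as.character(seq)
  chars <- strsplit(s, "")[[1]]
  masked <- if (mask == "skip") chars %in% c("a", "c", "g", "t", "n") else
    rep(FALSE, length(chars))
  codes <- match(toupper(chars), DNA_BASES)  # NA for N and others
  empty <- data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(), p = numeric())
  if (pwm$width > length(codes)) return(empty)
  out <- list()
  fwd_tab <- pwm_score_table(pwm, background, granularity)
  h <- scan_one_strand(codes, masked, fwd_tab, pwm$width, p_threshold)
  if (!is.null(h)) { h$strand <- "+"; out[["+"]] <- h }
  # minus strand: score the reverse complement of each window with the same
  # table (single null distribution, FIMO-style, exact strand symmetry)
  comp <- c(4L, 3L, 2L, 1L)
  rc_tab <- fwd_tab
  rc_tab$K <- fwd_tab$K[rev(seq_len(pwm$width)), comp, drop = FALSE]
  rc_tab$S <- fwd_tab$S[rev(seq_len(pwm$width)), comp, drop = FALSE]
  h <- scan_one_strand(codes, masked, rc_tab, pwm$width, p_threshold)
  if (!is.null(h)) { h$strand <- "-"; out[["-"]] <- h }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res$motif_id <- pwm$motif_id
  res <- res[order(res$offset, res$strand),
             c("motif_id", "offset", "strand", "score", "p")]
  rownames(res) <- NULL
  res
}

#' Scan a set of region sequences with a motif library
#'
#' @param seqs Named character vector or `DNAStringSet` of region
#'   sequences (names become `region_id`).
#' @param motifs List of `pwm` objects.
#' @param p_threshold,background,mask,granularity See [scan_pwm()].
#' @return Combined hit data.frame with a `region_id` column.
#' @export
scan_regions <- function(seqs, motifs, p_threshold = 1e-4,
                         background = NULL, mask = "skip",
                         granularity = 1000L) {
  ids <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- if (is.null(ids)) sprintf("region_%d", seq_along(seqs)) else
    ids
  if (is.null(background)) background <- estimate_background(seqs)
  rows <- list()
  for (m in motifs) {
    for (id in names(seqs)) {
      h <- scan_pwm(seqs[[id]], m, p_threshold, background, mask,
                    granularity)
      if (nrow(h) > 0) {
        h$region_id <- id
        rows[[length(rows) + 1L]] <- h
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(motif_id = character(), offset = integer(),
                      strand = character(), score = numeric(), p = numeric(),
                      region_id = character()))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Mononucleotide background from a sequence set
#' @param seqs Character vector of sequences.
#' @return Named frequency vector over A, C, G, T (uniform fallback when
#'   no unambiguous base is present).
#' @export
estimate_background <- function(seqs) {
  chars <- toupper(unlist(strsplit(paste(seqs, collapse = ""), "")))
  tab <- table(factor(chars, levels = DNA_BASES))
  if (sum(tab) == 0) return(setNames(rep(0.25, 4), DNA_BASES))
  setNames(as.numeric(tab) / sum(tab), DNA_BASES)
}

#' Known-motif enrichment of foreground vs background regions
#'
#' A region counts as hit by a motif when it contains at least one scan
#' hit at the p-value threshold. Per motif, hit-region counts in
#' foreground and background are compared by a one-sided Fisher exact test
#' (enrichment in foreground); q-values are BH across tested motifs.
#' Motifs wider than every foreground region are flagged untestable.
#'
#' @param fg_seqs,bg_seqs Named character vectors (or `DNAStringSet`) of
#'   foreground and background region sequences (repeat-masked lowercase
#'   honoured).
#' @param motifs List of `pwm` objects.
#' @param p_threshold Scan threshold (default 1e-4).
#' @param background Base frequencies; defaults to the background set's
#'   mononucleotide frequencies.
#' @return data.frame sorted by `q`: `motif_id`, `tf_name`,
#'   `fg_hit_regions`, `fg_total`, `bg_hit_regions`, `bg_total`,
#'   `odds_ratio`, `p`, `q`, `testable`.
#' @export
enrich_motifs <- function(fg_seqs, bg_seqs, motifs, p_threshold = 1e-4,
                          background = NULL) {
  fg_seqs <- as.character(fg_seqs)
  bg_seqs <- as.character(bg_seqs)
  stopifnot(length(fg_seqs) > 0, length(bg_seqs) > 0)
  if (is.null(background)) background <- estimate_background(bg_seqs)
  rows <- lapply(motifs, function(m) {
    testable <- any(nchar(fg_seqs) >= m$width)
    if (!testable) {
      return(data.frame(motif_id = m$motif_id, tf_name = m$tf_name,
                        fg_hit_regions = NA_integer_,
                        fg_total = length(fg_seqs),
                        bg_hit_regions = NA_integer_,
                        bg_total = length(bg_seqs),
                        odds_ratio = NA_real_, p = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    fg_hit <- sum(vapply(fg_seqs, function(s)
      nrow(scan_pwm(s, m, p_threshold, background)) > 0, logical(1)))
    bg_hit <- sum(vapply(bg_seqs, function(s)
      nrow(scan_pwm(s, m, p_threshold, background)) > 0, logical(1)))
    tab <- matrix(c(fg_hit, length(fg_seqs) - fg_hit,
                    bg_hit, length(bg_seqs) - bg_hit), 2)
    ft <- stats::fisher.test(tab, alternative = "greater")
    data.frame(motif_id = m$motif_id, tf_name = m$tf_name,
               fg_hit_regions = fg_hit, fg_total = length(fg_seqs),
               bg_hit_regions = bg_hit, bg_total = length(bg_seqs),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               testable = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  res$q[res$testable] <- bh(res$p[res$testable])
  res <- res[order(res$q), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Condition-specific LMRs of a tolerant sample
#'
#' LMRs of the tolerant sample with zero bp overlap against its paired
#' susceptible sample's LMRs; optionally intersected (>= 1 bp) with
#' hypomethylated DMRs of the same comparison.
#'
#' @param lmrs_tolerant,lmrs_susceptible LMR data.frames.
#' @param hypo_dmrs Optional DMR data.frame (only rows with
#'   `direction == "hypo"` are used when the column is present).
#' @return Subset of `lmrs_tolerant`.
#' @export
tolerant_specific_lmrs <- function(lmrs_tolerant, lmrs_susceptible,
                                   hypo_dmrs = NULL) {
  flags <- overlap_count(lmrs_tolerant, lmrs_susceptible)$flags
  out <- lmrs_tolerant[!flags, , drop = FALSE]
  if (!is.null(hypo_dmrs)) {
    if ("direction" %in% names(hypo_dmrs)) {
      hypo_dmrs <- hypo_dmrs[hypo_dmrs$direction == "hypo", , drop = FALSE]
    }
    out <- out[overlap_count(out, hypo_dmrs)$flags, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Extract region sequences from a genome
#'
#' @param genome `DNAStringSet` or path to a FASTA file (lowercase
#'   masking preserved).
#' @param regions Region data.frame; the `lmr_id`/`name` column (if any)
#'   names the output.
#' @return Named character vector of sequences.
#' @export
region_sequences <- function(genome, regions) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  names(genome) <- sub("\\s.*", "", names(genome))
  ids <- if ("lmr_id" %in% names(regions)) regions$lmr_id
         else if ("name" %in% names(regions)) regions$name
         else sprintf("region_%d", seq_len(nrow(regions)))
  out <- vapply(seq_len(nrow(regions)), function(i) {
    as.character(Biostrings::subseq(genome[[regions$chrom[i]]],
                                    start = regions$start[i] + 1L,
                                    end = regions$end[i]))
  }, character(1))
  setNames(out, ids)
}
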