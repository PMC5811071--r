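# CRAC / CARC cholesterol-recognition consensus motif scanning.
#
# CRAC: L/V - X(1-5) - Y    - X(1-5) - K/R   (N- to C-terminal)
# CARC: K/R - X(1-5) - Y/F  - X(1-5) - L/V   (the mirrored variant)
# The unknown residue X is tolerated in spacers but never matches an anchor.

.motif_def <- list(
  CRAC = list(first = c("L", "V"), central = "Y", last = c("K", "R")),
  CARC = list(first = c("K", "R"), central = c("Y", "F"), last = c("L", "V")))

#' Scan a protein sequence for CRAC/CARC motifs
#'
#' Enumerates every substring matching a motif class (all spacer-length
#' combinations 1-5 on each side), deduplicated by (class, start, end) and
#' sorted by start then end. All matches are reported, not only
#' leftmost-longest.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet (`X`
#'   tolerated; it never matches an anchor).
#' @param classes Motif classes to scan, subset of `c("CRAC", "CARC")`.
#' @return data.frame of hits: `class`, `start`, `end` (1-based inclusive),
#'   `match`, and anchor positions `anchor_branched`, `anchor_aromatic`,
#'   `anchor_basic` (for CARC the branched/basic roles are mirrored but the
#'   columns keep the role meaning: branched = L/V, basic = K/R).
#' @export
scan_motifs <- function(sequence, classes = c("CRAC", "CARC")) {
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "")[[1]]
  legal <- c(LETTERS[!LETTERS %in% c("B", "J", "O", "U", "Z")])
  bad <- which(!chars %in% legal)
  if (length(bad) > 0) {
    stop(mp_error("format", "illegal character '%s' at position %d",
                  chars[bad[1]], bad[1]))
  }
  n <- length(chars)
  hits <- list()
  for (cl in classes) {
    def <- .motif_def[[cl]]
    if (is.null(def)) stop(mp_error("config", "unknown motif class '%s'", cl))
    starts <- which(chars %in% def$first)
    for (s in starts) {
      for (d1 in 1:5) {
        cpos <- s + 1 + d1
        if (cpos > n || !chars[cpos] %in% def$central) next
        for (d2 in 1:5) {
          e <- cpos + 1 + d2
          if (e > n) break
          if (!chars[e] %in% def$last) next
          anchors <- if (cl == "CRAC") c(s, cpos, e) else c(e, cpos, s)
          hits[[length(hits) + 1]] <- data.frame(
            class = cl, start = s, end = e,
            match = substr(sequence, s, e),
            anchor_branched = anchors[1], anchor_aromatic = anchors[2],
            anchor_basic = anchors[3], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(class = character(), start = integer(),
                      end = integer(), match = character(),
                      anchor_branched = integer(), anchor_aromatic = integer(),
                      anchor_basic = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[!duplicated(out[, c("class", "start", "end")]), ]
  out <- out[order(out$start, out$end, out$class), ]
  rownames(out) <- NULL
  out
}

#' Scan the records of a FASTA file
#'
#' @param path FASTA file (single or multi-record).
#' @param classes Motif classes, see [scan_motifs()].
#' @return data.frame of hits with a leading `record` column.
#' @export
scan_fasta_motifs <- function(path, classes = c("CRAC", "CARC")) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop(mp_error("config", "Biostrings is required for FASTA input"))
  }
  seqs <- Biostrings::readAAStringSet(path)
  do.call(rbind, lapply(seq_along(seqs), function(i) {
    h <- scan_motifs(as.character(seqs[[i]]), classes)
    if (nrow(h) == 0) return(NULL)
    cbind(record = names(seqs)[i], h, stringsAsFactors = FALSE)
  }))
}

#' Merge overlapping same-class hits (presentation option)
#'
#' @param hits A [scan_motifs()] data.frame.
#' @return data.frame with columns `class`, `start`, `end`, one row per
#'   merged run of overlapping hits.
#' @export
merge_motif_hits <- function(hits) {
  out <- lapply(split(hits, hits$class), function(h) {
    h <- h[order(h$start, h$end), ]
    s <- h$start[1]; e <- h$end[1]
    rows <- list()
    for (i in seq_len(nrow(h))[-1]) {
      if (h$start[i] <= e) {
        e <- max(e, h$end[i])
      } else {
        rows[[length(rows) + 1]] <- c(s, e)
        s <- h$start[i]; e <- h$end[i]
      }
    }
    rows[[length(rows) + 1]] <- c(s, e)
    data.frame(class = h$class[1],
               start = vapply(rows, `[`, numeric(1), 1),
               end = vapply(rows, `[`, numeric(1), 2))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of motif hits with segments and binding sites
#'
#' Residue-interval intersection of each hit with each named segment (e.g.
#' TM helices) and each binding site, in the numbering of the scanned
#' sequence. A segment "contains" a motif when they share at least one
#' residue.
#'
#' @param hits A [scan_motifs()] data.frame.
#' @param segments Named list of `c(start, end)` residue ranges.
#' @param sites Optional list of `BindingSite`s or named residue-range
#'   vectors; sites given as `BindingSite` use `range(resno)`.
#' @param seq_length Optional sequence length; hits beyond it are an error
#'   (numbering mismatch).
#' @return List: `table` (one row per hit x segment with `overlap` length
#'   and `contains` flag) and `summary` (per segment, classes with >= 1
#'   overlapping hit).
#' @export
overlap_report <- function(hits, segments, sites = NULL, seq_length = NULL) {
  if (!is.null(seq_length) && nrow(hits) > 0 &&
      any(hits$end > seq_length | hits$start < 1)) {
    stop(mp_error("format", "hit outside sequence bounds (1..%d)",
                  seq_length))
  }
  ranges <- segments
  if (!is.null(sites)) {
    for (i in seq_along(sites)) {
      s <- sites[[i]]
      rng <- if (inherits(s, "BindingSite")) range(s$resno) else s
      ranges[[sprintf("site%s", if (inherits(s, "BindingSite")) s$id else i)]] <-
        rng
    }
  }
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    for (nm in names(ranges)) {
      r <- ranges[[nm]]
      ov <- max(0, min(hits$end[i], r[2]) - max(hits$start[i], r[1]) + 1)
      rows[[length(rows) + 1]] <- data.frame(
        class = hits$class[i], start = hits$start[i], end = hits$end[i],
        segment = nm, overlap = ov, contains = ov >= 1,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(class = character(), start = integer(), end = integer(),
               segment = character(), overlap = integer(),
               contains = logical())
  summ <- lapply(names(ranges), function(nm) {
    sub <- tab[tab$segment == nm & tab$contains, ]
    unique(sub$class)
  })
  names(summ) <- names(ranges)
  list(table = tab, summary = summ)
}
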