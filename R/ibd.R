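#' Read refinedIBD-format segment output
#'
#' Tab-separated columns: ind1, hap1, ind2, hap2, chrom, start_bp, end_bp,
#' LOD, length_cM.
#'
#' @param path file path.
#' @return data frame of IBD segments with columns `ind_a`, `ind_b`, `chrom`,
#'   `start_cm`, `end_cm`, `length_cm`, `lod` (genetic positions are taken
#'   from the cM length anchored at the bp start scaled by 1e-6, which
#'   preserves ordering and gaps for downstream merging).
#' @export
read_refined_ibd <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- c("ind1", "hap1", "ind2", "hap2", "chrom", "start_bp",
                 "end_bp", "lod", "length_cm")
  start_cm <- df$start_bp * 1e-6
  data.frame(ind_a = as.character(df$ind1), ind_b = as.character(df$ind2),
             chrom = as.character(df$chrom),
             start_cm = start_cm, end_cm = start_cm + df$length_cm,
             length_cm = df$length_cm, lod = df$lod,
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Merge nearby IBD segments per individual pair and chromosome
#'
#' Fuses segments of the same (unordered) individual pair on the same
#' chromosome whenever the gap between them is at most `gap_cm`
#' centimorgans; fusion is transitive, so a chain of close segments becomes
#' one block spanning the union, and overlapping segments always fuse. An
#' optional `consistency_fun(block_a, block_b)` hook can veto a fusion (e.g.
#' by checking genotypes across the gap against a genotype source); the
#' default merge is purely gap-based.
#'
#' @param segs data frame with `ind_a`, `ind_b`, `chrom`, `start_cm`,
#'   `end_cm`.
#' @param gap_cm maximum gap to fuse across (default 0.6).
#' @param consistency_fun optional function of the two candidate rows
#'   returning `TRUE` to allow the fusion.
#' @return merged data frame with recomputed `length_cm`.
#' @export
merge_segments <- function(segs, gap_cm = 0.6, consistency_fun = NULL) {
  if (nrow(segs) == 0) return(segs)
  stopifnot(all(segs$end_cm > segs$start_cm))
  key <- paste(pair_key(segs$ind_a, segs$ind_b), segs$chrom, sep = "#")
  out <- lapply(split(seq_len(nrow(segs)), key), function(ii) {
    s <- segs[ii, , drop = FALSE]
    s <- s[order(s$start_cm), , drop = FALSE]
    merged <- s[1, , drop = FALSE]
    for (i in seq_len(nrow(s))[-1]) {
      last <- nrow(merged)
      gap <- s$start_cm[i] - merged$end_cm[last]
      fuse <- gap <= gap_cm
      if (fuse && !is.null(consistency_fun)) {
        fuse <- isTRUE(consistency_fun(merged[last, ], s[i, ]))
      }
      if (fuse) {
        merged$end_cm[last] <- max(merged$end_cm[last], s$end_cm[i])
      } else {
        merged <- rbind(merged, s[i, , drop = FALSE])
      }
    }
    merged
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$length_cm <- out$end_cm - out$start_cm
  out
}

#' Bin merged IBD segments into length classes
#'
#' Classes `[1, 5)`, `[5, 10)` and `[10, Inf)` cM, which proxy contact
#' roughly 2,500-1,500, 1,500-500 and 500-0 years ago respectively; segments
#' shorter than 1 cM are discarded.
#'
#' @param segs merged segment data frame with `length_cm`.
#' @return named list of data frames: `"1-5"`, `"5-10"`, `">10"`.
#' @export
bin_by_length <- function(segs) {
  len <- segs$length_cm
  list(
    "1-5"  = segs[len >= 1 & len < 5, , drop = FALSE],
    "5-10" = segs[len >= 5 & len < 10, , drop = FALSE],
    ">10"  = segs[len >= 10, , drop = FALSE]
  )
}

#' Default minimum shared-block counts per length class
#'
#' Short segments are noisier, so the 1-5 cM class requires 4 shared blocks
#' per pair; longer classes require 2.
#'
#' @param class length-class label.
#' @return integer threshold.
#' @export
default_min_blocks <- function(class) {
  if (class == "1-5") 4L else 2L
}

#' Cross-population IBD sharing probabilities
#'
#' For one length class: an individual pair counts as connected when it
#' shares at least `min_blocks` segments of that class; the sharing
#' probability for populations A and B is the number of connected
#' cross-population pairs divided by all possible dyads `n_A * n_B` — the
#' probability that an individual drawn at random from A shares IBD of that
#' length with one drawn at random from B. Within-population sharing (over
#' `n (n - 1) / 2` dyads) is reported when `within = TRUE`.
#'
#' @param class_segs segment data frame for one length class.
#' @param pop_labels named character vector mapping individual id to
#'   population.
#' @param min_blocks connection threshold (see [default_min_blocks()]).
#' @param within include within-population rows.
#' @return data frame with `pop_a`, `pop_b`, `connected_pairs`,
#'   `possible_dyads`, `probability`.
#' @export
sharing_network <- function(class_segs, pop_labels, min_blocks = 2L,
                            within = FALSE) {
  pops <- sort(unique(pop_labels))
  sizes <- table(factor(pop_labels, levels = pops))
  if (any(sizes == 0)) warning("population(s) with zero individuals skipped")
  if (nrow(class_segs) > 0) {
    pk <- pair_key(class_segs$ind_a, class_segs$ind_b)
    counts <- table(pk)
    connected <- names(counts)[counts >= min_blocks]
  } else {
    connected <- character(0)
  }
  conn_pop <- if (length(connected)) {
    parts <- strsplit(connected, "|", fixed = TRUE)
    a <- pop_labels[vapply(parts, `[`, "", 1)]
    b <- pop_labels[vapply(parts, `[`, "", 2)]
    paste(pmin(a, b), pmax(a, b), sep = "|")
  } else character(0)
  combos <- utils::combn(pops, 2, simplify = FALSE)
  if (within) combos <- c(combos, lapply(pops, function(p) c(p, p)))
  rows <- lapply(combos, function(pr) {
    na <- sizes[[pr[1]]]; nb <- sizes[[pr[2]]]
    dyads <- if (pr[1] == pr[2]) na * (na - 1) / 2 else na * nb
    if (dyads == 0) return(NULL)
    k <- sum(conn_pop == paste(pr[1], pr[2], sep = "|"))
    data.frame(pop_a = pr[1], pop_b = pr[2], connected_pairs = k,
               possible_dyads = dyads, probability = k / dyads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
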