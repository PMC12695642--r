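# Synapse-detectability scoring: annotation-node census via single-link
# clustering at a merge radius, census/query matching, false-positive
# hotspots, annotator score cleaning, and confusion-matrix metrics
# (P, R, F1, F_beta with beta = 2 by default).

.node_positions <- function(nodes) {
  as.matrix(nodes[, c("z_nm", "y_nm", "x_nm")])
}

# single-link cluster labels for points within `radius`; strict single-link
# chaining (a <= radius link anywhere merges clusters)
.single_link <- function(pos, radius) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::dist(pos), method = "single")
  stats::cutree(hc, h = radius)
}

#' Build a synapse census from annotation nodes
#'
#' Nodes seeded within `merge_radius_nm` of each other (single-link: chains
#' merge) are assumed to point to the same synapse. Each census entry keeps
#' the centroid of its member nodes and the earliest pass at which any
#' member was seeded.
#'
#' @param nodes data.frame with columns `z_nm`, `y_nm`, `x_nm` and
#'   optionally `pass_index`, `annotator_id`, `modality`, `dendrite_id`.
#' @param merge_radius_nm merge radius in nm (> 0, default 300).
#' @return object of class `synapse_census`: data.frame `entries`
#'   (z_nm, y_nm, x_nm centroid, n_members, first_pass_detected,
#'   dendrite_id if present) plus `members` (list of row indices into
#'   `nodes`) and `merge_radius`.
#' @export
build_census <- function(nodes, merge_radius_nm = 300) {
  if (merge_radius_nm <= 0) stop("merge_radius_nm must be > 0")
  if (nrow(nodes) == 0) {
    return(structure(list(entries = data.frame(z_nm = numeric(0),
                                               y_nm = numeric(0),
                                               x_nm = numeric(0),
                                               n_members = integer(0),
                                               first_pass_detected = integer(0)),
                          members = list(), merge_radius = merge_radius_nm),
                     class = "synapse_census"))
  }
  pos <- .node_positions(nodes)
  if (any(!is.finite(pos))) stop("node positions must be finite")
  cl <- .single_link(pos, merge_radius_nm)
  ids <- sort(unique(cl))
  members <- lapply(ids, function(i) which(cl == i))
  cent <- t(vapply(members, function(m)
    colMeans(pos[m, , drop = FALSE]), numeric(3)))
  fp <- if ("pass_index" %in% names(nodes)) {
    vapply(members, function(m) min(nodes$pass_index[m]), numeric(1))
  } else rep(NA_integer_, length(members))
  entries <- data.frame(z_nm = cent[, 1], y_nm = cent[, 2], x_nm = cent[, 3],
                        n_members = lengths(members),
                        first_pass_detected = as.integer(fp))
  if ("dendrite_id" %in% names(nodes)) {
    entries$dendrite_id <- vapply(members, function(m) {
      dv <- nodes$dendrite_id[m]
      dv[which.max(tabulate(match(dv, unique(dv))))]
    }, nodes$dendrite_id[1])
  }
  structure(list(entries = entries, members = members,
                 merge_radius = merge_radius_nm),
            class = "synapse_census")
}

#' @export
print.synapse_census <- function(x, ...) {
  cat("<synapse_census> ", nrow(x$entries), " entries (merge radius ",
      x$merge_radius, " nm)\n", sep = "")
  invisible(x)
}

#' Match query nodes against a census
#'
#' A census entry counts as detected iff at least one query node lies within
#' `radius_nm` (Euclidean) of its centroid. Query nodes matching no entry
#' are returned as false-positive candidates.
#'
#' @param census a `synapse_census`.
#' @param query_nodes data.frame with `z_nm`, `y_nm`, `x_nm` (plus optional
#'   columns carried through).
#' @param radius_nm match radius, nm (> 0, default 300).
#' @return list: `detected` logical per census entry, `detection_pass`
#'   (earliest `pass_index` among matching query nodes, NA when undetected
#'   or absent), `unmatched` (rows of `query_nodes` matching no entry).
#' @export
match_detections <- function(census, query_nodes, radius_nm = 300) {
  if (radius_nm <= 0) stop("radius_nm must be > 0")
  ne <- nrow(census$entries)
  nq <- nrow(query_nodes)
  if (nq == 0) {
    return(list(detected = rep(FALSE, ne),
                detection_pass = rep(NA_integer_, ne),
                unmatched = query_nodes))
  }
  cent <- .node_positions(census$entries)
  qp <- .node_positions(query_nodes)
  detected <- rep(FALSE, ne)
  detection_pass <- rep(NA_integer_, ne)
  q_matched <- rep(FALSE, nq)
  if (ne > 0) {
    for (i in seq_len(ne)) {
      d2 <- colSums((t(qp) - cent[i, ])^2)
      hit <- which(d2 <= radius_nm^2)
      if (length(hit)) {
        detected[i] <- TRUE
        q_matched[hit] <- TRUE
        if ("pass_index" %in% names(query_nodes))
          detection_pass[i] <- min(query_nodes$pass_index[hit])
      }
    }
  }
  list(detected = detected, detection_pass = detection_pass,
       unmatched = query_nodes[!q_matched, , drop = FALSE])
}

#' Find false-positive hotspots among unmatched nodes
#'
#' Single-link clusters of unmatched annotation tags; clusters receiving at
#' least `min_tags` tags within the radius are hotspots for confusion.
#'
#' @param unmatched_nodes data.frame with `z_nm`, `y_nm`, `x_nm`.
#' @param radius_nm cluster radius, nm (default 300).
#' @param min_tags minimum tags per hotspot (>= 2).
#' @return data.frame of hotspots: centroid coordinates and `n_tags`.
#' @export
find_hotspots <- function(unmatched_nodes, radius_nm = 300, min_tags = 2) {
  if (min_tags < 2) stop("min_tags must be >= 2")
  if (nrow(unmatched_nodes) == 0)
    return(data.frame(z_nm = numeric(0), y_nm = numeric(0),
                      x_nm = numeric(0), n_tags = integer(0)))
  pos <- .node_positions(unmatched_nodes)
  cl <- .single_link(pos, radius_nm)
  sz <- table(cl)
  keep <- as.integer(names(sz)[sz >= min_tags])
  if (!length(keep))
    return(data.frame(z_nm = numeric(0), y_nm = numeric(0),
                      x_nm = numeric(0), n_tags = integer(0)))
  cent <- t(vapply(keep, function(i)
    colMeans(pos[cl == i, , drop = FALSE]), numeric(3)))
  data.frame(z_nm = cent[, 1], y_nm = cent[, 2], x_nm = cent[, 3],
             n_tags = as.integer(sz[as.character(keep)]))
}

#' Clean an annotator score array
#'
#' Two-stage QC mirroring the captcha analysis: (1) annotators whose
#' reference-modality (EM) score vector correlates below `min_xcorr`
#' (Pearson, strict `<`) with the mean of the other annotators are removed;
#' (2) regions with any missing response (0) among the retained annotators
#' in either modality are dropped.
#'
#' @param score_array a `score_array` (or bare region x annotator x modality
#'   integer array with values 0-4).
#' @param min_xcorr correlation threshold (default 0.4, as for the 3
#'   annotator task; 0.3 was used for the 5 annotator task).
#' @return list: `scores` (cleaned array), `kept_annotators`,
#'   `dropped_annotators`, `kept_regions`, `dropped_regions`.
#' @export
clean_scores <- function(score_array, min_xcorr = 0.4) {
  scores <- if (inherits(score_array, "score_array"))
    score_array$scores else score_array
  if (any(!(scores %in% 0:4))) stop("scores must be integers in 0..4")
  na <- dim(scores)[2]
  complete <- apply(scores != 0, 1, all)   # rows usable for correlation
  keep <- rep(TRUE, na)
  if (na >= 3) {
    for (a in seq_len(na)) {
      others <- setdiff(which(keep), a)
      va <- scores[complete, a, 1]
      vo <- rowMeans(scores[complete, others, 1, drop = FALSE])
      r <- suppressWarnings(stats::cor(va, vo))
      if (!is.na(r) && r < min_xcorr) keep[a] <- FALSE
    }
  }
  if (sum(keep) < 2) stop("fewer than 2 annotators remain after QC")
  sub <- scores[, keep, , drop = FALSE]
  region_ok <- apply(sub != 0, 1, all)
  list(scores = sub[region_ok, , , drop = FALSE],
       kept_annotators = which(keep),
       dropped_annotators = which(!keep),
       kept_regions = which(region_ok),
       dropped_regions = which(!region_ok))
}

#' Confusion-matrix detection metrics
#'
#' @param TP,FP,FN,TN counts.
#' @param beta recall weight for `F_beta` (default 2: recall weighted
#'   higher than precision).
#' @return object of class `confusion_summary`: counts plus `precision`,
#'   `recall`, `f1`, `f_beta`, `beta`, and `precision_defined` /
#'   `recall_defined` flags. Undefined ratios are NA, never 0.
#' @export
confusion_summary <- function(TP, FP, FN, TN = 0, beta = 2) {
  precision <- if (TP + FP > 0) TP / (TP + FP) else NA_real_
  recall <- if (TP + FN > 0) TP / (TP + FN) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  fb <- if (!is.na(precision) && !is.na(recall) &&
            beta^2 * precision + recall > 0)
    (1 + beta^2) * precision * recall / (beta^2 * precision + recall)
  else NA_real_
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 precision = precision, recall = recall, f1 = f1,
                 f_beta = fb, beta = beta,
                 precision_defined = TP + FP > 0,
                 recall_defined = TP + FN > 0),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat("<confusion_summary> TP=", x$TP, " FP=", x$FP, " FN=", x$FN,
      " TN=", x$TN, "\n  P=", format(x$precision, digits = 4),
      " R=", format(x$recall, digits = 4),
      " F1=", format(x$f1, digits = 4),
      " F", x$beta, "=", format(x$f_beta, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Captcha-task confusion analysis
#'
#' Per region, the mean score of each modality is computed over annotators;
#' means `>= cut` are binarized to "synapse" (the reference modality, EM, is
#' modality 1; PXCT, modality 2, is the prediction). Also tabulates the
#' 4 x 4 table of rounded mean EM score (ties away from zero) against the
#' distribution of individual PXCT scores.
#'
#' @param cleaned_scores cleaned array (region x annotator x modality) or
#'   the list from [clean_scores()].
#' @param cut binarization cut in (1, 4); means >= cut count as synapse
#'   (default 2.5).
#' @param beta F_beta weight (default 2).
#' @return list: `summary` (a `confusion_summary`), `table_2x2`,
#'   `table_4x4` (EM bin rows x PXCT score columns), `region_means`
#'   (data.frame em, pxct, em_bin, px_bin).
#' @export
captcha_confusion <- function(cleaned_scores, cut = 2.5, beta = 2) {
  scores <- if (is.list(cleaned_scores) && !is.null(cleaned_scores$scores))
    cleaned_scores$scores else cleaned_scores
  if (length(scores) == 0 || dim(scores)[1] == 0) stop("empty score array")
  if (cut <= 1 || cut >= 4) stop("cut must lie in (1, 4)")
  em_mean <- apply(scores[, , 1, drop = FALSE], 1, mean)
  px_mean <- apply(scores[, , 2, drop = FALSE], 1, mean)
  em_bin <- em_mean >= cut
  px_bin <- px_mean >= cut
  TP <- sum(em_bin & px_bin); FP <- sum(!em_bin & px_bin)
  FN <- sum(em_bin & !px_bin); TN <- sum(!em_bin & !px_bin)
  t22 <- matrix(c(TP, FN, FP, TN), 2, 2,
                dimnames = list(pxct = c("synapse", "no_synapse"),
                                em = c("synapse", "no_synapse")))
  # rounded mean EM score, ties away from zero, vs PXCT score distribution
  em_round <- pmin(pmax(floor(em_mean + 0.5), 1), 4)
  t44 <- matrix(0L, 4, 4, dimnames = list(em_bin = 1:4, pxct_score = 1:4))
  for (r in seq_along(em_round)) {
    for (s in scores[r, , 2]) {
      t44[em_round[r], s] <- t44[em_round[r], s] + 1L
    }
  }
  list(summary = confusion_summary(TP, FP, FN, TN, beta = beta),
       table_2x2 = t22, table_4x4 = t44,
       region_means = data.frame(em = em_mean, pxct = px_mean,
                                 em_bin = em_bin, px_bin = px_bin))
}

#' Dendrite-centric synapse detection report
#'
#' Builds the reference (EM) census from `em_nodes`, matches the PXCT nodes
#' against it, and tabulates per-pass discovery: the fraction of census
#' entries first seeded at each pass (EM) and, among detected entries, the
#' fraction first tagged at each pass in the PXCT data. Percentages are
#' rounded to the nearest integer. Pooled and per-dendrite counts are
#' reported; false-positive hotspots among unmatched PXCT nodes are
#' included.
#'
#' @param em_nodes,px_nodes annotation node data.frames (`z_nm`, `y_nm`,
#'   `x_nm`, `pass_index`, optional `dendrite_id`).
#' @param merge_radius_nm census merge / match radius, nm (default 300).
#' @return list: `census`, `n_census`, `n_detected`, `em_pass_counts`,
#'   `em_pass_pct`, `px_pass_counts`, `px_pass_pct`, `detected_fraction`,
#'   `per_dendrite` (data.frame, when dendrite ids are present),
#'   `hotspots`.
#' @export
dendrite_report <- function(em_nodes, px_nodes, merge_radius_nm = 300) {
  census <- build_census(em_nodes, merge_radius_nm)
  m <- match_detections(census, px_nodes, merge_radius_nm)
  n_census <- nrow(census$entries)
  passes <- sort(unique(c(em_nodes$pass_index, px_nodes$pass_index)))
  em_counts <- vapply(passes, function(p)
    sum(census$entries$first_pass_detected == p), integer(1))
  names(em_counts) <- passes
  em_pct <- round(100 * em_counts / max(n_census, 1))
  det_pass <- m$detection_pass[m$detected]
  px_counts <- vapply(passes, function(p) sum(det_pass == p, na.rm = TRUE),
                      integer(1))
  names(px_counts) <- passes
  n_det <- sum(m$detected)
  px_pct <- round(100 * px_counts / max(n_det, 1))
  per_dendrite <- NULL
  if ("dendrite_id" %in% names(census$entries)) {
    ids <- unique(census$entries$dendrite_id)
    per_dendrite <- do.call(rbind, lapply(ids, function(d) {
      sel <- census$entries$dendrite_id == d
      data.frame(dendrite_id = d, n_census = sum(sel),
                 n_detected = sum(m$detected[sel]),
                 detected_fraction = mean(m$detected[sel]))
    }))
  }
  list(census = census, n_census = n_census, n_detected = n_det,
       em_pass_counts = em_counts, em_pass_pct = em_pct,
       px_pass_counts = px_counts, px_pass_pct = px_pct,
       detected_fraction = if (n_census) n_det / n_census else NA_real_,
       per_dendrite = per_dendrite,
       hotspots = find_hotspots(m$unmatched, merge_radius_nm))
}
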