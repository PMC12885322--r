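# Condition-comparison analytics: subsystem-average flux tables and log2
# flux ratios with top-k up/down lists.

#' Subsystem-average flux table across conditions
#'
#' Mean absolute collapsed net flux per subsystem per condition, plus a
#' row-normalized (min-max) twin in \[0, 1\]; constant rows normalize to 0.5.
#'
#' @param solutions Named list of `integration_solution`s (or any objects with a
#'   `flux_net` vector), one per condition.
#' @param net The `irreversible_network` the solutions were computed on.
#' @return list(mean = subsystems x conditions matrix,
#'   normalized = row-normalized twin).
#' @export
subsystem_table <- function(solutions, net) {
  stopifnot(length(solutions) >= 1L, inherits(net, "irreversible_network"))
  orig <- net$original_reaction_ids
  prov <- net$provenance
  sub <- vapply(orig, function(r)
    unname(net$subsystem[which(prov$orig_id == r)[1]]), character(1))
  conds <- names(solutions)
  subs <- sort(unique(sub))
  m <- matrix(0, length(subs), length(conds), dimnames = list(subs, conds))
  for (cd in conds) {
    v <- abs(solutions[[cd]]$flux_net[orig])
    m[, cd] <- tapply(v, sub, mean)[subs]
  }
  rmin <- apply(m, 1, min); rmax <- apply(m, 1, max)
  norm <- m
  for (i in seq_len(nrow(m))) {
    norm[i, ] <- if (rmax[i] - rmin[i] > 0) {
      (m[i, ] - rmin[i]) / (rmax[i] - rmin[i])
    } else 0.5
  }
  list(mean = m, normalized = norm)
}

#' Log2 flux ratios between two conditions
#'
#' `score = log2(max(v_treat, floor) / max(v_control, floor))` on absolute
#' fluxes. Reactions where both fluxes fall below the floor are excluded and
#' flagged rather than reported as a fake log-ratio of 0.
#'
#' @param v_control,v_treat Named numeric flux vectors (same ids).
#' @param floor Flux floor guarding the ratio (default 1e-6).
#' @return data.frame(reaction, control, treat, score, flagged); flagged rows
#'   carry `NA` scores.
#' @export
log_ratio <- function(v_control, v_treat, floor = 1e-6) {
  stopifnot(length(v_control) == length(v_treat))
  ids <- names(v_control)
  if (is.null(ids)) ids <- paste0("R", seq_along(v_control))
  vc <- abs(as.numeric(v_control)); vt <- abs(as.numeric(v_treat))
  flagged <- vc < floor & vt < floor
  score <- log2(pmax(vt, floor) / pmax(vc, floor))
  score[flagged] <- NA_real_
  data.frame(reaction = ids, control = vc, treat = vt,
             score = score, flagged = flagged, stringsAsFactors = FALSE)
}

#' Top-k most up- and down-regulated reactions
#'
#' The k largest and k smallest log-ratio scores; ties are broken by reaction
#' id (lexicographic) so the output is deterministic. Flagged (NA) entries
#' are ignored; fewer than k scored reactions yield shorter lists.
#'
#' @param scores A [log_ratio()] data.frame (or any with `reaction`, `score`).
#' @param k List length (default 10).
#' @return list(up, down): data.frames sorted by score (descending /
#'   ascending).
#' @export
top_k <- function(scores, k = 10) {
  stopifnot(k >= 1)
  ok <- scores[!is.na(scores$score), , drop = FALSE]
  up <- ok[order(-ok$score, ok$reaction), , drop = FALSE]
  down <- ok[order(ok$score, ok$reaction), , drop = FALSE]
  list(up = utils::head(up[, c("reaction", "score")], k),
       down = utils::head(down[, c("reaction", "score")], k))
}
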