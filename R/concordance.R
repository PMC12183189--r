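# Transcript-metabolite concordance: for each significantly changed
# metabolite, ask whether the transcripts of its mapped enzymatic steps
# moved in a direction that explains the change.  Orientation comes from
# the map's `role` column: for an accumulating metabolite, consistent
# evidence is a synthesis step up, a degradation step down, or a
# competing (flux-diverting) step down; mirrored for a depleting
# metabolite.

#' Read a metabolite-to-enzyme-transcript map
#'
#' Tab-separated with columns `metabolite`, `step` (reaction label),
#' `role` (`synthesis`, `degradation`, or `competing`), `transcript`.
#'
#' @param path TSV file path.
#' @return Data frame with those columns.
#' @export
read_enzyme_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "step", "role", "transcript")
  if (!all(need %in% names(df))) {
    stop("enzyme map must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(df$role), c("synthesis", "degradation", "competing"))
  if (length(bad)) {
    stop("unknown enzyme roles: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Classify the concordance of one metabolite change
#'
#' @param metabolite metabolite id.
#' @param region region label.
#' @param direction `"up"` or `"down"`: the sign of the significant
#'   metabolite change.
#' @param dats data frame of transcript changes with columns `transcript`,
#'   `region`, `log2fc`.
#' @param map enzyme map from [read_enzyme_map()].
#' @param dat_threshold magnitude a transcript change must reach to count
#'   as differential (default 1, the relaxed `|log2FC| >= 1` tier).
#' @return List of class `concordance_call` with `metabolite`, `region`,
#'   `class` (one of `transcriptionally_coordinated`, `metabolic_control`,
#'   `discordant`, `unmapped`), and `evidence` (the mapped transcript rows
#'   with their fold changes and consistency).
#' @export
classify_concordance <- function(metabolite, region, direction,
                                 dats, map, dat_threshold = 1) {
  direction <- match.arg(direction, c("up", "down"))
  steps <- map[map$metabolite == metabolite, , drop = FALSE]
  if (!nrow(steps)) {
    return(structure(list(metabolite = metabolite, region = region,
                          class = "unmapped",
                          evidence = NULL),
                     class = "concordance_call"))
  }
  d <- dats[dats$region == region, c("transcript", "log2fc"), drop = FALSE]
  ev <- merge(steps, d, by = "transcript", all.x = TRUE)
  ev$passes <- !is.na(ev$log2fc) & abs(ev$log2fc) >= dat_threshold
  sign_needed <- ifelse(ev$role == "synthesis", 1, -1)
  if (direction == "down") sign_needed <- -sign_needed
  ev$consistent <- ev$passes & sign(ev$log2fc) == sign_needed
  cls <- if (any(ev$consistent)) {
    "transcriptionally_coordinated"
  } else if (!any(ev$passes)) {
    "metabolic_control"
  } else {
    "discordant"
  }
  structure(list(metabolite = metabolite, region = region, class = cls,
                 evidence = ev),
            class = "concordance_call")
}

#' @export
print.concordance_call <- function(x, ...) {
  cat(sprintf("<concordance_call> %s / %s: %s\n",
              x$metabolite, x$region, x$class))
  if (!is.null(x$evidence)) {
    print(x$evidence[, c("step", "role", "transcript", "log2fc",
                         "consistent")])
  }
  invisible(x)
}

#' Concordance ledger for a differential metabolite table
#'
#' Applies [classify_concordance()] to every significant row of a
#' differential table.
#'
#' @param dams differential table (e.g. from [dam_pipeline()]) with
#'   columns `feature`, `region`, `log2fc`, `significant`.
#' @param dats transcript table with columns `transcript`, `region`,
#'   `log2fc`.
#' @param map enzyme map from [read_enzyme_map()].
#' @param dat_threshold passed to [classify_concordance()].
#' @return Data frame with columns `metabolite`, `region`, `direction`,
#'   `class`, `supporting_transcripts`.
#' @export
concordance_table <- function(dams, dats, map, dat_threshold = 1) {
  sig <- dams[dams$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(metabolite = character(0), region = character(0),
                      direction = character(0), class = character(0),
                      supporting_transcripts = character(0)))
  }
  rows <- lapply(seq_len(nrow(sig)), function(i) {
    dir <- if (sig$log2fc[i] > 0) "up" else "down"
    call <- classify_concordance(sig$feature[i], sig$region[i], dir,
                                 dats, map, dat_threshold)
    supp <- if (is.null(call$evidence)) "" else
      paste(call$evidence$transcript[call$evidence$consistent],
            collapse = ";")
    data.frame(metabolite = sig$feature[i], region = sig$region[i],
               direction = dir, class = call$class,
               supporting_transcripts = supp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
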