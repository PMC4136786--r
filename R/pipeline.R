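# End-to-end convenience wrappers over the processing stages.

#' Run a processing pipeline on a synthetic library and count alleles
#'
#' The three pipelines mirror increasing levels of error suppression:
#' \describe{
#'   \item{raw}{each mate aligned independently, duplicates removed by
#'     the start-only key; no masking or boosting.}
#'   \item{merge}{overlapping mates merged (discordance masked, quality
#'     boosted to 45), duplicates removed by the start-only key.}
#'   \item{consensus}{merged reads collapsed per length-aware duplicate
#'     family into consensus reads (quality boosted to 50).}
#' }
#'
#' @param library a `cfdna_library` from [simulate_library()].
#' @param pipeline which processing level to apply.
#' @param sites site table to count at (default: the library's own).
#' @param cutoff per-base quality cutoff for counting.
#' @param sample_id label carried into the counts.
#' @return list with `fragments` (the processed alignments) and
#'   `counts` (per-site allele counts from [count_alleles()]).
#' @export
run_pipeline <- function(library,
                         pipeline = c("consensus", "merge", "raw"),
                         sites = library$sites, cutoff = 0L,
                         sample_id = NA) {
  pipeline <- match.arg(pipeline)
  frags <- pipeline_fragments(library, pipeline)
  list(fragments = frags,
       counts = count_alleles(frags, sites, cutoff = cutoff,
                              sample_id = sample_id))
}

#' Processed alignments for one pipeline level
#'
#' @inheritParams run_pipeline
#' @return an aligned-fragments data.frame.
#' @export
pipeline_fragments <- function(library,
                               pipeline = c("consensus", "merge", "raw")) {
  pipeline <- match.arg(pipeline)
  if (pipeline == "raw") {
    return(mark_only(place_raw_reads(library)))
  }
  merged <- merge_pairs(library$reads)$merged
  frags <- place_reads(merged, library)
  if (pipeline == "merge") mark_only(frags) else consensus_reads(frags)
}
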