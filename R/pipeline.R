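#' @include clustering.R
NULL

#' Run the full pose-processing pipeline on a docking campaign
#'
#' Applies, in order: overlap-duplicate removal, per-pose assessment and
#' selection (contact count and ring-axis tilt; skipped when the criteria
#' are disabled), pooled threshold clustering across studies, and the
#' cross-study consensus filter.
#'
#' @param campaign a [DockingCampaign-class], or a plain list of
#'   [Pose-class] objects.
#' @param structure the prepared [OrientedStructure-class] docked against.
#' @param criteria a [SelectionCriteria-class] (default: transmembrane
#'   criteria enabled).
#' @param duplicateRmsd box-overlap duplicate threshold, Angstrom
#'   (default 1).
#' @param rmsdCutoff clustering threshold, Angstrom (default 4).
#' @param nStudiesRequired studies required for consensus (default: the
#'   campaign's study count, or 5 for a plain pose list).
#' @param withinStudyPrecluster if TRUE, poses are first clustered within
#'   each study and only the per-study representatives are pooled for the
#'   cross-study clustering (default FALSE: pool directly).
#' @return A list with \code{consensus} (a [ConsensusSet-class]),
#'   \code{clusters}, \code{assessments} (per-pose verdict table),
#'   \code{selected} (poses surviving dedup and selection) and
#'   \code{table} (the [clusterTable()] of the consensus partition).
#' @export
sweepCampaign <- function(campaign, structure,
                          criteria = selectionCriteria(),
                          duplicateRmsd = 1, rmsdCutoff = 4,
                          nStudiesRequired = NULL,
                          withinStudyPrecluster = FALSE) {
  poseList <- if (is(campaign, "DockingCampaign")) campaign@poses
              else campaign
  if (is.null(nStudiesRequired))
    nStudiesRequired <- if (is(campaign, "DockingCampaign"))
      campaign@nStudies else 5L
  poseList <- dedupeOverlapPoses(poseList, duplicateRmsd)
  assessments <- if (length(poseList))
    assessPoses(poseList, structure, criteria) else NULL
  selected <- if (length(poseList)) poseList[assessments$passes] else list()
  pool <- selected
  if (withinStudyPrecluster && length(selected)) {
    studyOf <- vapply(selected, function(p) p@studyId, integer(1))
    pool <- list()
    for (st in sort(unique(studyOf))) {
      cl <- thresholdCluster(selected[studyOf == st], rmsdCutoff)
      pool <- c(pool, lapply(cl, function(x) x@representative))
    }
  }
  clusters <- thresholdCluster(pool, rmsdCutoff)
  consensus <- consensusFilter(clusters, nStudiesRequired)
  list(consensus = consensus, clusters = clusters,
       assessments = assessments, selected = selected,
       table = clusterTable(consensus))
}
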