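#' @include AllClasses.R
NULL

setMethod("show", "MembraneFrame", function(object) {
  cat(sprintf(
    "MembraneFrame: z = [%.2f, %.2f] A, thickness %.2f A, normal +z\n",
    object@zLower, object@zUpper, object@thickness))
})

setMethod("show", "OrientedStructure", function(object) {
  at <- object@atoms
  cat(sprintf(
    "OrientedStructure: %d atoms (%d protein, %d dummy, %d pseudo)\n",
    nrow(at), sum(.proteinRows(at)), length(object@dummyIndices),
    sum(at$pseudo)))
  show(object@frame)
})

setMethod("show", "SearchBox", function(object) {
  cat(sprintf(
    "SearchBox %s-%d: center (%.1f, %.1f, %.1f), size (%.1f, %.1f, %.1f) A\n",
    object@half, object@index, object@center[1], object@center[2],
    object@center[3], object@size[1], object@size[2], object@size[3]))
})

setMethod("show", "Pose", function(object) {
  cat(sprintf(
    "Pose %s [study %d, run %d, box %s, model %d]: %.2f kcal/mol, %d atoms\n",
    object@ligandName, object@studyId, object@runId, object@boxId,
    object@modelId, object@energy, nrow(object@atoms)))
})

setMethod("show", "DockingCampaign", function(object) {
  cat(sprintf(
    "DockingCampaign (%s regime): %d poses, %d studies x %d runs, boxes: %s\n",
    object@regime@label, length(object@poses), object@nStudies,
    object@nRuns, paste(object@boxIds, collapse = ", ")))
})

setMethod("show", "PoseCluster", function(object) {
  cat(sprintf(
    "PoseCluster: %d member(s), studies {%s}, representative %.2f kcal/mol\n",
    length(object@members), paste(object@studiesPresent, collapse = ","),
    object@representative@energy))
})

setMethod("show", "ConsensusSet", function(object) {
  cat(sprintf(
    "ConsensusSet: %d accepted, %d rejected (>= %d studies required)\n",
    length(object@accepted), length(object@rejected),
    object@nStudiesRequired))
})

setMethod("show", "Speciation", function(object) {
  cat(sprintf(
    paste0("Speciation (xChol = %.4g): xS %.4g, xI %.4g, xSI %.4g, ",
           "xSIchol %.4g, xIchol %.4g\n"),
    object@params@xChol, object@xS, object@xI, object@xSI, object@xSIchol,
    object@xIchol))
  cat(sprintf("  max |residual| = %.2e\n", max(abs(object@residuals))))
})
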