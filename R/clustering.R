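#' @include selection.R
NULL

#' Root-mean-square deviation between two poses
#'
#' Computed over matched heavy atoms (paired by atom name) in the common
#' receptor frame, without superposition: superposing would erase the
#' spatial distinctness of binding sites.
#'
#' @param p1,p2 [Pose-class] objects with identical ligand topology (the
#'   same set of heavy-atom names).
#' @return rmsd in Angstrom.
#' @examples
#' # identical poses have rmsd 0; a rigid (3,0,0) shift has rmsd 3
#' @export
poseRmsd <- function(p1, p2) {
  a1 <- .heavyAtoms(p1)
  a2 <- .heavyAtoms(p2)
  idx <- match(a1$name, a2$name)
  if (anyNA(idx) || nrow(a1) != nrow(a2) || anyDuplicated(a1$name))
    stop("atom-name mismatch: poses do not share a ligand topology")
  d2 <- (a1$x - a2$x[idx])^2 + (a1$y - a2$y[idx])^2 + (a1$z - a2$z[idx])^2
  sqrt(mean(d2))
}

#' Simple threshold clustering of poses
#'
#' One-pass leader clustering: poses are sorted by ascending energy (ties
#' broken by study, run, box, model order); each pose joins the first
#' existing cluster whose representative lies within \code{rmsdCutoff}, and
#' otherwise seeds a new cluster with itself as representative. Seeding by
#' best energy makes the representative rule (the energetically most
#' favourable member represents the cluster) consistent with membership, and
#' guarantees every member lies within the cutoff of its representative.
#'
#' @param poseList list of [Pose-class] objects sharing a ligand topology.
#' @param rmsdCutoff clustering threshold in Angstrom (default 4).
#' @return A list of [PoseCluster-class] objects; every input pose is
#'   assigned to exactly one cluster. Empty input gives an empty list.
#' @export
thresholdCluster <- function(poseList, rmsdCutoff = 4) {
  if (!length(poseList)) return(list())
  ord <- .poseOrder(poseList)
  reps <- integer(0)          # indices (into poseList) of cluster seeds
  membership <- integer(length(poseList))
  for (i in ord) {
    assigned <- 0L
    for (k in seq_along(reps)) {
      if (poseRmsd(poseList[[i]], poseList[[reps[k]]]) < rmsdCutoff) {
        assigned <- k
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, i)
      assigned <- length(reps)
    }
    membership[i] <- assigned
  }
  lapply(seq_along(reps), function(k) {
    mem <- poseList[membership == k]
    studies <- sort(unique(vapply(mem, function(p) p@studyId, integer(1))))
    new("PoseCluster", members = mem, representative = poseList[[reps[k]]],
        studiesPresent = studies, rmsdCutoff = as.numeric(rmsdCutoff))
  })
}

#' @rdname members
setMethod("members", "PoseCluster", function(x) x@members)

#' @rdname representative
setMethod("representative", "PoseCluster", function(x) x@representative)

#' @rdname studiesPresent
setMethod("studiesPresent", "PoseCluster", function(x) x@studiesPresent)

#' Cross-study consensus filter
#'
#' Partitions clusters into accepted and rejected: a cluster is accepted iff
#' it contains a member from at least \code{nStudiesRequired} distinct
#' studies (with the default of five studies and five required, this is the
#' rule that a cluster must contain a member from each study).
#'
#' @param clusters list of [PoseCluster-class] objects built from poses
#'   pooled across studies.
#' @param nStudiesRequired number of distinct studies required (default 5).
#' @return A [ConsensusSet-class].
#' @export
consensusFilter <- function(clusters, nStudiesRequired = 5L) {
  nStudiesRequired <- as.integer(nStudiesRequired)
  if (nStudiesRequired < 1L)
    stop("nStudiesRequired must be at least 1")
  ok <- vapply(clusters,
               function(cl) length(cl@studiesPresent) >= nStudiesRequired,
               logical(1))
  new("ConsensusSet", accepted = clusters[ok], rejected = clusters[!ok],
      nStudiesRequired = nStudiesRequired)
}

#' @rdname acceptedClusters
setMethod("acceptedClusters", "ConsensusSet", function(x) x@accepted)

#' @rdname rejectedClusters
setMethod("rejectedClusters", "ConsensusSet", function(x) x@rejected)

#' Tabulate clusters
#'
#' @param clusters list of [PoseCluster-class] objects, or a
#'   [ConsensusSet-class] (accepted and rejected are tabulated with an
#'   \code{accepted} column).
#' @return data.frame with one row per cluster: id, size, studies (comma
#'   separated), representative energy and representative ring-centroid
#'   coordinates.
#' @export
clusterTable <- function(clusters) {
  accepted <- NULL
  if (is(clusters, "ConsensusSet")) {
    accepted <- c(rep(TRUE, length(clusters@accepted)),
                  rep(FALSE, length(clusters@rejected)))
    clusters <- c(clusters@accepted, clusters@rejected)
  }
  if (!length(clusters))
    return(data.frame(id = integer(), size = integer(), studies = character(),
                      repEnergy = numeric(), x = numeric(), y = numeric(),
                      z = numeric()))
  tab <- do.call(rbind, lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    ctr <- colMeans(ringCoords(cl@representative))
    data.frame(id = i, size = length(cl@members),
               studies = paste(cl@studiesPresent, collapse = ","),
               repEnergy = cl@representative@energy,
               x = ctr[1], y = ctr[2], z = ctr[3],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(accepted)) tab$accepted <- accepted
  rownames(tab) <- NULL
  tab
}
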