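#' @rdname PeptideTrajectory-class
#' @param object,x an object.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname PeptideSystem-class
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))

#' @rdname PeptideSystem-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname PeptideSystem-class
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))

#' @rdname PeptideSystem-class
#' @export
setGeneric("atomData", function(x) standardGeneric("atomData"))

#' @rdname PeptideTrajectory-class
#' @param i frame index.
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' @rdname PeptideTrajectory-class
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname SSAssignment-class
#' @export
setGeneric("ssCodes", function(x) standardGeneric("ssCodes"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterCenters", function(x) standardGeneric("clusterCenters"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))

#' @rdname ClusterResult-class
#' @export
setGeneric("clusterPopulations",
           function(x) standardGeneric("clusterPopulations"))

#' @rdname Landscape-class
#' @export
setGeneric("pmfMatrix", function(x) standardGeneric("pmfMatrix"))

#' @rdname Landscape-class
#' @export
setGeneric("probabilityMatrix",
           function(x) standardGeneric("probabilityMatrix"))

#' @rdname OligomerClass-class
#' @export
setGeneric("oligomerLabel", function(x) standardGeneric("oligomerLabel"))

#' @rdname OligomerClass-class
#' @export
setGeneric("strandCounts", function(x) standardGeneric("strandCounts"))
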