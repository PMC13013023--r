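#' @rdname Reconstruction-class
#' @param x,object a `Reconstruction`.
#' @export
setGeneric("swcSamples", function(x) standardGeneric("swcSamples"))

#' @rdname Reconstruction-class
#' @export
setGeneric("cellID", function(x) standardGeneric("cellID"))

#' @rdname Reconstruction-class
#' @export
setGeneric("cellLabel", function(x) standardGeneric("cellLabel"))

#' @rdname BranchTree-class
#' @param x,object a `BranchTree`.
#' @export
setGeneric("branchTable", function(x) standardGeneric("branchTable"))

#' @rdname BranchTree-class
#' @export
setGeneric("nBranches", function(x) standardGeneric("nBranches"))

#' @rdname BranchTree-class
#' @export
setGeneric("tips", function(x) standardGeneric("tips"))

#' @rdname BranchTree-class
#' @export
setGeneric("branchChildren", function(x) standardGeneric("branchChildren"))

#' @rdname BranchTree-class
#' @export
setGeneric("leafNumbers", function(x) standardGeneric("leafNumbers"))

#' @rdname BranchTree-class
#' @export
setGeneric("maxLeafNumber", function(x) standardGeneric("maxLeafNumber"))

#' @rdname BranchTree-class
#' @export
setGeneric("relLeafNumbers", function(x) standardGeneric("relLeafNumbers"))

#' @rdname ScaleSchedule-class
#' @param x,object a `ScaleSchedule`.
#' @export
setGeneric("nLevels", function(x) standardGeneric("nLevels"))

#' @rdname ScaleSchedule-class
#' @export
setGeneric("terminalResistance",
  function(x) standardGeneric("terminalResistance")
)

#' @rdname ComparisonReport-class
#' @param x,object a `ComparisonReport`.
#' @export
setGeneric("aucTable", function(x) standardGeneric("aucTable"))

#' @rdname ComparisonReport-class
#' @export
setGeneric("accuracyTable", function(x) standardGeneric("accuracyTable"))
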