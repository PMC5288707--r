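#' @rdname TemporalNetwork-accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname TemporalNetwork-accessors
#' @export
setGeneric("numSnapshots", function(x) standardGeneric("numSnapshots"))

#' @rdname TemporalNetwork-accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname TemporalNetwork-accessors
#' @export
setGeneric("snapshotWidth", function(x) standardGeneric("snapshotWidth"))

#' @rdname TemporalNetwork-accessors
#' @export
setGeneric("snapshotList", function(x) standardGeneric("snapshotList"))

#' @rdname snapshotAt-TemporalNetwork-method
#' @export
setGeneric("snapshotAt",
  function(x, t, boundary = c("periodic", "truncate"))
    standardGeneric("snapshotAt"))

#' @rdname aggregateNetwork-TemporalNetwork-method
#' @export
setGeneric("aggregateNetwork", function(x) standardGeneric("aggregateNetwork"))

#' @rdname CentralityScores-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname CentralityScores-accessors
#' @export
setGeneric("scoreMethod", function(x) standardGeneric("scoreMethod"))
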