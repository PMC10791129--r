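#' @rdname MultichannelStack-class
#' @param x a \linkS4class{MultichannelStack}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname MultichannelStack-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname MultichannelStack-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname CalciumTraceSet-class
#' @export
setGeneric("cellType", function(x) standardGeneric("cellType"))

#' @rdname CalciumTraceSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
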