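#' @name fragcharge-accessors
#' @title Accessors for fragcharge classes
#' @description Accessor generics for \linkS4class{MolecularGraph},
#'   \linkS4class{FragmentLibrary}, \linkS4class{FragmentMatch},
#'   \linkS4class{MatchReport}, \linkS4class{ChargeState} and
#'   \linkS4class{MissingFragment}.
#' @param x object
#' @param value replacement value
NULL

#' @rdname fragcharge-accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("netCharge", function(x) standardGeneric("netCharge"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("numAtoms", function(x) standardGeneric("numAtoms"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("numBonds", function(x) standardGeneric("numBonds"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("partialCharges", function(x) standardGeneric("partialCharges"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("partialCharges<-",
           function(x, value) standardGeneric("partialCharges<-"))

#' @rdname fragcharge-accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))
#' @rdname fragcharge-accessors
#' @param id library id
#' @export
setGeneric("libEntry", function(x, id) standardGeneric("libEntry"))

#' @rdname fragcharge-accessors
#' @export
setGeneric("queryAtoms", function(x) standardGeneric("queryAtoms"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("refAtoms", function(x) standardGeneric("refAtoms"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("shellAtoms", function(x) standardGeneric("shellAtoms"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("fragmentSize", function(x) standardGeneric("fragmentSize"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("fragmentCharge", function(x) standardGeneric("fragmentCharge"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("libraryId", function(x) standardGeneric("libraryId"))

#' @rdname fragcharge-accessors
#' @export
setGeneric("matches", function(x) standardGeneric("matches"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("coverage", function(x) standardGeneric("coverage"))

#' @rdname fragcharge-accessors
#' @export
setGeneric("resolvedCharges", function(x) standardGeneric("resolvedCharges"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("atomStatus", function(x) standardGeneric("atomStatus"))
#' @rdname fragcharge-accessors
#' @export
setGeneric("targetCharge", function(x) standardGeneric("targetCharge"))

#' @rdname fragcharge-accessors
#' @export
setGeneric("coreAtoms", function(x) standardGeneric("coreAtoms"))
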