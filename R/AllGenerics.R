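#' @name accessors
#' @title Accessors for CMETrace classes
#' @description Slot accessors: prefer these over direct `@` access.
#' @param x an object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("organism", function(x) standardGeneric("organism"))
#' @rdname accessors
#' @export
setMethod("organism", "Proteome", function(x) x@organism)

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname accessors
#' @export
setMethod("sequences", "Proteome", function(x) x@sequences)
#' @rdname accessors
#' @export
setMethod("sequences", "SeedAlignment", function(x) x@rows)

#' @rdname accessors
#' @export
setGeneric("taxonPath", function(x) standardGeneric("taxonPath"))
#' @rdname accessors
#' @export
setMethod("taxonPath", "Proteome", function(x) x@taxonPath)

#' @rdname accessors
#' @export
setGeneric("focalPath", function(x) standardGeneric("focalPath"))
#' @rdname accessors
#' @export
setMethod("focalPath", "Taxonomy", function(x) x@focalPath)
#' @rdname accessors
#' @export
setMethod("focalPath", "EmergenceMatrix", function(x) x@focalPath)

#' @rdname accessors
#' @export
setGeneric("cladeLeaves", function(x) standardGeneric("cladeLeaves"))
#' @rdname accessors
#' @export
setMethod("cladeLeaves", "Taxonomy", function(x) x@cladeLeaves)

#' @rdname accessors
#' @export
setGeneric("profileLength", function(x) standardGeneric("profileLength"))
#' @rdname accessors
#' @export
setMethod("profileLength", "ProfileHMM", function(x) x@M)

#' @rdname accessors
#' @export
setGeneric("matchEmissions", function(x) standardGeneric("matchEmissions"))
#' @rdname accessors
#' @export
setMethod("matchEmissions", "ProfileHMM", function(x) x@matchEmis)

#' @rdname accessors
#' @export
setGeneric("background", function(x) standardGeneric("background"))
#' @rdname accessors
#' @export
setMethod("background", "ProfileHMM", function(x) x@bg)

#' @rdname accessors
#' @export
setGeneric("callStatus", function(x) standardGeneric("callStatus"))
#' @rdname accessors
#' @export
setMethod("callStatus", "HomologCall", function(x) x@status)

#' @rdname accessors
#' @export
setGeneric("callHits", function(x) standardGeneric("callHits"))
#' @rdname accessors
#' @export
setMethod("callHits", "HomologCall", function(x) x@hits)

#' @rdname accessors
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))
#' @rdname accessors
#' @export
setMethod("presence", "EmergenceMatrix", function(x) x@presence)

#' @rdname accessors
#' @export
setGeneric("cladePresence", function(x) standardGeneric("cladePresence"))
#' @rdname accessors
#' @export
setMethod("cladePresence", "EmergenceMatrix", function(x) x@cladePresence)

#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setMethod("epochs", "EmergenceMatrix", function(x) x@epochs)

#' @rdname accessors
#' @export
setGeneric("interactionGraph", function(x) standardGeneric("interactionGraph"))
#' @rdname accessors
#' @export
setMethod("interactionGraph", "PINGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setMethod("atomTable", "StructureModel", function(x) x@atoms)

setMethod("show", "Proteome", function(object) {
  cat("Proteome of", object@organism, "with", length(object@sequences),
      "proteins\n")
  if (length(object@taxonPath))
    cat("  taxon path:", paste(object@taxonPath, collapse = " > "), "\n")
})

setMethod("show", "SeedAlignment", function(object) {
  cat("SeedAlignment", object@id, ":", length(object@rows), "rows x",
      if (length(object@rows)) Biostrings::width(object@rows)[1] else 0,
      "columns\n")
})

setMethod("show", "Taxonomy", function(object) {
  cat("Taxonomy with", length(object@tree$tip.label), "organisms and",
      length(object@cladeLeaves), "named clades\n")
  cat("  focal path:", paste(object@focalPath, collapse = " > "), "\n")
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM", object@id, "with", object@M, "match states (seed:",
      object@seedId, ")\n")
})

setMethod("show", "EvalueCalibration", function(object) {
  cat(sprintf("EvalueCalibration for %s: mu = %.3f, lambda = %.3f (n = %d)\n",
              object@profileId, object@mu, object@lambda, object@nNull))
})

setMethod("show", "HomologCall", function(object) {
  cat(sprintf("HomologCall %s / %s: %s (%d hit(s), %d accepted)\n",
              object@family, object@organism, object@status,
              nrow(object@hits),
              if (nrow(object@hits)) sum(object@hits$accepted) else 0L))
})

setMethod("show", "EmergenceMatrix", function(object) {
  cat("EmergenceMatrix:", nrow(object@presence), "families x",
      ncol(object@presence), "organisms\n")
  for (f in rownames(object@presence))
    cat(sprintf("  %-12s %s\n", f, object@epochs[[f]]))
})

setMethod("show", "PINGraph", function(object) {
  cat("PINGraph with", igraph::vcount(object@graph), "nodes and",
      igraph::ecount(object@graph), "edges\n")
})

setMethod("show", "StructureModel", function(object) {
  a <- object@atoms
  cat("StructureModel:", nrow(a), "heavy atoms,",
      length(unique(paste(a$chain, a$resno))), "residues,",
      length(unique(a$chain)), "chain(s)\n")
})
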