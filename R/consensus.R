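#' Decision thresholds for the consensus engine
#'
#' Species-level ANI thresholds are context dependent: 90 percent for the
#' genus Cupriavidus and for the species R. pickettii (both unusually
#' diverse), 95 percent for the rest of Ralstonia. The genus boundary is a
#' mean POCP of 60 percent.
#'
#' @param ani_cupriavidus,ani_r_pickettii,ani_ralstonia_default percent ANI
#'   thresholds per context.
#' @param pocp_genus percent POCP genus boundary.
#' @return a named list of thresholds.
#' @export
thresholdConfig <- function(ani_cupriavidus = 90, ani_r_pickettii = 90,
                            ani_ralstonia_default = 95, pocp_genus = 60) {
    stopifnot(ani_cupriavidus > 0, ani_cupriavidus < 100,
              ani_ralstonia_default > 0, ani_ralstonia_default < 100,
              pocp_genus > 0, pocp_genus < 100)
    list(ani_species_threshold = c(Cupriavidus = ani_cupriavidus,
                                   R_pickettii = ani_r_pickettii,
                                   Ralstonia_default = ani_ralstonia_default),
         pocp_genus_threshold = pocp_genus)
}

#' Convert an ANI matrix to a clustering distance matrix
#'
#' `d = 1 - ANI/100` on the fractional scale, diagonal 0. Missing (no
#' signal) entries are an error: clustering refuses to impute.
#'
#' @param m an [ANIMatrix-class] or a plain symmetric percent matrix.
#' @return a symmetric non-negative distance matrix.
#' @export
aniToDistance <- function(m) {
    v <- if (methods::is(m, "ANIMatrix")) aniValues(m) else m
    if (any(is.na(v)))
        stop("ANI matrix has missing (no-signal) entries; ",
             "clustering requires a complete matrix")
    d <- 1 - v / 100
    diag(d) <- 0
    d
}

#' Cut UPGMA clusters of (1 - ANI) at a percent-identity threshold
#'
#' Builds (or reuses) the average-linkage dendrogram of the `1 - ANI/100`
#' distances and extracts the maximal subtrees whose merge height is
#' strictly below `1 - threshold/100`: strains in one cluster are linked at
#' ANI above the threshold. Singletons are allowed; cluster ids are assigned
#' by decreasing size, ties by first-seen strain order. Raising the
#' threshold never merges clusters.
#'
#' @param x an [ANIMatrix-class], a distance matrix from [aniToDistance()],
#'   or an `hclust`/UPGMA tree produced by [upgmaTree()].
#' @param threshold percent ANI threshold (e.g. 90 or 95).
#' @return named integer vector: strain id -> cluster id.
#' @export
cutClusters <- function(x, threshold) {
    hc <- if (inherits(x, "hclust")) x
          else if (inherits(x, "phylo") && !is.null(attr(x, "hclust"))) attr(x, "hclust")
          else {
              d <- if (methods::is(x, "ANIMatrix")) {
                  aniToDistance(x)
              } else if (is.matrix(x) && nrow(x) > 0 &&
                         all(abs(diag(x) - 100) < 1e-9)) {
                  aniToDistance(x)   # percent ANI matrix
              } else x               # already a distance matrix
              stats::hclust(stats::as.dist(d), method = "average")
          }
    h_cut <- 1 - threshold / 100
    n <- length(hc$labels)
    # merge groups strictly below the cut height
    grp <- -seq_len(n)                      # leaf i starts in group -i
    node_grp <- integer(nrow(hc$merge))
    nxt <- 0L
    for (k in seq_len(nrow(hc$merge))) {
        if (hc$height[[k]] < h_cut) {
            nxt <- nxt + 1L
            left <- hc$merge[k, 1]; right <- hc$merge[k, 2]
            lg <- if (left < 0) grp[-left] else node_grp[left]
            rg <- if (right < 0) grp[-right] else node_grp[right]
            grp[grp == lg | grp == rg] <- nxt
            node_grp[k] <- nxt
        } else node_grp[k] <- 0L
    }
    membership <- stats::setNames(grp, hc$labels)
    # relabel by size descending, ties by first occurrence
    sizes <- table(membership)
    first <- vapply(names(sizes), function(cl)
        which(membership == cl)[1], integer(1))
    ord <- names(sizes)[order(-as.integer(sizes), first)]
    stats::setNames(match(as.character(membership), ord), hc$labels)
}

#' Per-strain evidence table for the 150-strain reference panel
#'
#' Loads the packaged evidence table covering all 150 strains of the
#' curated Cupriavidus/Ralstonia panel: current classification, type-strain
#' flag, phylotype, ANI cluster, tetranucleotide (TNA) cluster, POCP genus
#' call, and the 16S/MLSA clade labels. For strains of the R. solanacearum
#' species complex whose phylotype-based renaming was already accepted
#' before this panel was assembled, the current name is recorded as the
#' accepted one; this transcription choice is documented in the file
#' header.
#'
#' @return a data.frame with one row per strain.
#' @export
evidenceFixture <- function() {
    path <- system.file("extdata", "evidence_cupriavidus_ralstonia.tsv",
                        package = "taxongauge", mustWork = TRUE)
    utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                      na.strings = c("NA", ""))
}

.fullName <- function(genus, species) {
    ifelse(is.na(species) | species == "sp.", paste(genus, "sp."),
           paste(genus, species))
}

.isRealSpecies <- function(species) !is.na(species) & species != "sp."

# Panel-level annotation: anchor each named species to one ANI cluster
# (its type strain's cluster, else the cluster holding most of its
# current members, first-seen on ties) and record each cluster's anchored
# species with their modal TNA cluster.
.annotateEvidence <- function(ev) {
    stopifnot(all(c("strain_id", "current_genus", "current_species",
                    "type_strain", "ani_cluster", "tna_cluster",
                    "pocp_genus") %in% names(ev)))
    if (anyDuplicated(ev$strain_id))
        stop("duplicate strain ids in evidence table")
    ev$full_current <- .fullName(ev$current_genus, ev$current_species)
    real <- .isRealSpecies(ev$current_species)

    species_anchor <- list()   # full species name -> cluster id
    anchor_tna <- list()       # full species name -> modal TNA of anchor members
    for (sp in unique(ev$full_current[real])) {
        rows <- which(ev$full_current == sp & real)
        typed <- rows[ev$type_strain[rows] %in% TRUE &
                      !is.na(ev$ani_cluster[rows])]
        cl <- if (length(typed)) {
            ev$ani_cluster[typed[1]]
        } else {
            cls <- ev$ani_cluster[rows]
            cls <- cls[!is.na(cls)]
            if (!length(cls)) next
            tab <- table(cls)
            top <- names(tab)[tab == max(tab)]
            # tie: cluster of the first-listed strain of this species
            first_cl <- as.character(cls[1])
            if (first_cl %in% top) first_cl else top[1]
        }
        species_anchor[[sp]] <- cl
        members <- rows[ev$ani_cluster[rows] %in% cl]
        tnas <- ev$tna_cluster[members]
        tnas <- tnas[!is.na(tnas)]
        anchor_tna[[sp]] <- if (length(tnas)) names(sort(table(tnas),
                                                         decreasing = TRUE))[1]
                            else NA_character_
    }

    cluster_species <- split(names(species_anchor),
                             unlist(species_anchor, use.names = FALSE))
    cluster_size <- table(ev$ani_cluster[!is.na(ev$ani_cluster)])

    # strict-majority current species per TNA cluster (all real-named members)
    tna_majority <- vapply(unique(ev$tna_cluster[!is.na(ev$tna_cluster)]),
        function(t) {
            sp <- ev$full_current[real & ev$tna_cluster %in% t]
            if (!length(sp)) return(NA_character_)
            tab <- table(sp)
            if (max(tab) * 2 > sum(tab)) names(tab)[which.max(tab)]
            else NA_character_
        }, character(1))

    list(evidence = ev,
         species_anchor = species_anchor,
         anchor_tna = anchor_tna,
         cluster_species = cluster_species,
         cluster_size = cluster_size,
         tna_majority = tna_majority)
}

.splitName <- function(full) {
    if (is.na(full) || full == "other")
        return(c(NA_character_, NA_character_))
    parts <- strsplit(full, " ", fixed = TRUE)[[1]]
    c(parts[1], paste(parts[-1], collapse = " "))
}

.phylotypeSpecies <- function(phylotype) {
    if (is.na(phylotype)) return(NA_character_)
    p <- sub("-.*$", "", phylotype)
    if (p %in% c("IV")) return("syzygii")
    if (p %in% c("III")) return("pseudosolanacearum")
    if (grepl("^II", p)) return("solanacearum")
    if (p == "I") return("pseudosolanacearum")
    NA_character_
}

.SOLANACEARUM_COMPLEX <- c("solanacearum", "pseudosolanacearum", "syzygii")

# Decision for one annotated evidence row. `ann` is .annotateEvidence output.
.decideStrain <- function(e, ann, thresholds) {
    flags <- c(r16s = "unavailable", mlsa = "unavailable", ani = "unavailable",
               tna = "unavailable", pocp = "unavailable")

    ## (1) genus from POCP, falling back to the phylogenetic clades
    pocp <- e$pocp_genus
    genus <- if (!is.na(pocp) && !(pocp %in% c("neither", "ambiguous"))) {
        pocp
    } else if (!is.na(pocp) && pocp == "neither") {
        "other"
    } else {
        cand <- c(.splitName(e$r16s_label)[1], .splitName(e$mlsa_label)[1])
        cand <- cand[!is.na(cand)]
        if (!length(cand)) stop("no usable evidence for strain ", e$strain_id)
        names(sort(table(cand), decreasing = TRUE))[1]
    }

    species <- NA_character_
    ani_implied <- NA_character_  # what the ANI clusters alone would call
    if (genus != "other") {
        cl <- e$ani_cluster
        anchored <- if (!is.na(cl)) ann$cluster_species[[as.character(cl)]] else NULL
        anchored <- anchored[vapply(anchored, function(s)
            .splitName(s)[1] == genus, logical(1))]
        cur_full <- if (.isRealSpecies(e$current_species) &&
                        identical(e$current_genus, genus))
            .fullName(e$current_genus, e$current_species) else NA_character_

        if (!is.na(cur_full) && cur_full %in% anchored) {
            species <- e$current_species
            ani_implied <- species
        } else if (length(anchored) == 1) {
            s <- anchored[[1]]
            ani_implied <- .splitName(s)[2]
            # adopt the cluster's species only when the TNA signature agrees
            if (!is.na(e$tna_cluster) &&
                identical(e$tna_cluster, ann$anchor_tna[[s]]))
                species <- .splitName(s)[2]
        } else {
            ani_implied <- "sp."
        }
        if (is.na(species)) {
            # unanchored or disagreeing cluster; singletons may borrow the
            # species carried by their TNA cluster's clear majority
            singleton <- is.na(cl) ||
                (as.character(cl) %in% names(ann$cluster_size) &&
                 ann$cluster_size[[as.character(cl)]] == 1L)
            if (singleton && !is.na(e$tna_cluster)) {
                ts <- ann$tna_majority[[e$tna_cluster]]
                if (!is.na(ts) && .splitName(ts)[1] == genus)
                    species <- .splitName(ts)[2]
            }
            if (is.na(species)) species <- "sp."
        }

        ## (3) phylotype override inside the R. solanacearum species complex
        if (genus == "Ralstonia" &&
            (species %in% .SOLANACEARUM_COMPLEX ||
             e$current_species %in% .SOLANACEARUM_COMPLEX)) {
            ph <- .phylotypeSpecies(e$phylotype)
            if (!is.na(ph)) species <- ph
        }
    }

    proposed_full <- if (genus == "other") "other" else .fullName(genus, species)

    ## (4) agreement flags; ANI takes precedence, conflicts stay visible
    cmp <- function(label) {
        if (is.na(label)) return("unavailable")
        if (identical(label, proposed_full)) "agree" else "conflict"
    }
    flags[["r16s"]] <- cmp(e$r16s_label)
    flags[["mlsa"]] <- cmp(e$mlsa_label)
    flags[["pocp"]] <- if (is.na(pocp)) "unavailable"
        else if ((pocp == "neither" && genus == "other") ||
                 identical(pocp, genus)) "agree" else "conflict"
    flags[["ani"]] <- if (genus == "other" || is.na(e$ani_cluster)) "unavailable"
        else if (identical(ani_implied, species)) "agree" else "conflict"
    tna_sp <- if (!is.na(e$tna_cluster)) ann$tna_majority[[e$tna_cluster]]
              else NA_character_
    flags[["tna"]] <- if (is.na(tna_sp)) "unavailable"
        else if (identical(tna_sp, proposed_full)) "agree" else "conflict"

    changed <- if (genus == "other") !identical(e$current_genus, "other")
        else !(identical(genus, e$current_genus) &&
               identical(.fullName(genus, species), e$full_current))

    data.frame(strain_id = e$strain_id,
               current_genus = e$current_genus,
               current_species = e$current_species,
               proposed_genus = genus,
               proposed_species = if (genus == "other") NA_character_ else species,
               changed = changed,
               flag_16s = flags[["r16s"]], flag_mlsa = flags[["mlsa"]],
               flag_ani = flags[["ani"]], flag_tna = flags[["tna"]],
               flag_pocp = flags[["pocp"]],
               stringsAsFactors = FALSE)
}

#' Consensus reclassification decisions for a strain panel
#'
#' Applies the evidence-combination rules to every strain of an evidence
#' table (one row per strain, as returned by [evidenceFixture()] or
#' [buildEvidence()]):
#'
#' 1. *Genus* comes from the POCP call at the 60 percent boundary; a strain
#'    below the boundary for every genus is assigned to neither
#'    (`proposed_genus = "other"`); an ambiguous or missing call falls back
#'    to the majority genus of the 16S and MLSA clades.
#' 2. *Species* comes from the ANI clusters: each named species is anchored
#'    to one cluster (its type strain's cluster, else the cluster holding
#'    most of its current members). A strain keeps its species when its
#'    cluster anchors it; it adopts its cluster's anchored species when the
#'    tetranucleotide signature agrees; a strain in a cluster anchoring no
#'    species of its genus (including a strain separated from the cluster
#'    that anchors its current species) becomes `"<genus> sp."`. Strains in
#'    singleton clusters may instead borrow the species carried by a clear
#'    majority of their TNA cluster.
#' 3. Within the R. solanacearum species complex a recorded phylotype
#'    overrides: I and III give R. pseudosolanacearum, II gives
#'    R. solanacearum, IV gives R. syzygii.
#' 4. Per-method agreement flags (16S, MLSA, ANI, TNA, POCP) are reported as
#'    agree / conflict / unavailable against the final proposal; conflicts
#'    are never dropped silently.
#'
#' The decision for a strain depends only on the panel evidence, not on the
#' order of rows.
#'
#' @param evidence data.frame with columns `strain_id`, `current_genus`,
#'   `current_species`, `type_strain`, `phylotype`, `ani_cluster`,
#'   `tna_cluster`, `pocp_genus`, and optionally `r16s_label`, `mlsa_label`.
#' @param thresholds a [thresholdConfig()] list.
#' @return data.frame of decisions, one row per strain, with `changed`
#'   flagging strains whose proposal differs from the current name.
#' @export
decideClassification <- function(evidence, thresholds = thresholdConfig()) {
    if (!"r16s_label" %in% names(evidence)) evidence$r16s_label <- NA_character_
    if (!"mlsa_label" %in% names(evidence)) evidence$mlsa_label <- NA_character_
    ann <- .annotateEvidence(evidence)
    out <- do.call(rbind, lapply(seq_len(nrow(ann$evidence)), function(i)
        .decideStrain(ann$evidence[i, ], ann, thresholds)))
    rownames(out) <- NULL
    out
}

#' Count strains proposed for reclassification
#'
#' @param decisions data.frame from [decideClassification()].
#' @return number of strains with `changed = TRUE`.
#' @export
countReclassified <- function(decisions) {
    if (anyDuplicated(decisions$strain_id))
        stop("duplicate strain ids in decisions")
    sum(decisions$changed)
}

#' Assemble an evidence table from computed pipeline results
#'
#' Joins strain metadata with ANI clusters cut at the context-dependent
#' thresholds (Cupriavidus and clusters containing the R. pickettii type
#' strain at the relaxed threshold, remaining Ralstonia at the default),
#' TNA cluster labels and POCP genus calls, producing the evidence table
#' consumed by [decideClassification()].
#'
#' @param metadata data.frame with `strain_id`, `current_genus`,
#'   `current_species`, `type_strain`, `phylotype`.
#' @param ani an [ANIMatrix-class] over the same strains.
#' @param tna_clusters named character vector (strain -> TNA cluster label).
#' @param pocp_calls named character vector (strain -> genus call, one of the
#'   genus names, `"neither"`, `"ambiguous"`).
#' @param thresholds a [thresholdConfig()] list.
#' @return evidence data.frame.
#' @export
buildEvidence <- function(metadata, ani, tna_clusters, pocp_calls,
                          thresholds = thresholdConfig()) {
    ids <- metadata$strain_id
    stopifnot(all(ids %in% rownames(aniValues(ani))))
    thr <- thresholds$ani_species_threshold
    cl_lo <- cutClusters(ani, thr[["Cupriavidus"]])
    cl_hi <- cutClusters(ani, thr[["Ralstonia_default"]])
    pick_type <- ids[metadata$type_strain %in% TRUE &
                     metadata$current_species %in% "pickettii"]
    pick_lo <- if (length(pick_type)) cl_lo[[pick_type[1]]] else NA_integer_
    cluster_of <- vapply(ids, function(s) {
        relaxed <- identical(pocp_calls[[s]], "Cupriavidus") ||
            (!is.na(pick_lo) && cl_lo[[s]] == pick_lo)
        if (relaxed) paste0("lo.", cl_lo[[s]]) else paste0("hi.", cl_hi[[s]])
    }, character(1))
    data.frame(strain_id = ids,
               current_genus = metadata$current_genus,
               current_species = metadata$current_species,
               type_strain = metadata$type_strain,
               phylotype = metadata$phylotype,
               ani_cluster = unname(cluster_of),
               tna_cluster = unname(tna_clusters[ids]),
               pocp_genus = unname(pocp_calls[ids]),
               stringsAsFactors = FALSE)
}
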