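# Synaptic input-budget analysis and rule-based neuron classification from
# connectome synapse tables (neuPrint-style edge lists).

#' Per-partner input budget of target neurons
#'
#' For each target, the fraction of its total input synapse weight
#' contributed by each upstream partner, optionally restricted to synapses
#' on one postsynaptic compartment (the dendritic or axonal input budget).
#' Fractions over all partners sum to 1 per target. Targets with zero
#' inputs under the filter are flagged with a warning and omitted.
#'
#' @param synapses Synapse table: `data.frame(bodyid_pre, bodyid_post,
#'   compartment_post, weight)` (extra columns ignored).
#' @param targets Character/numeric vector of target body ids.
#' @param compartment `NULL` for the overall budget, or `"dendrite"` /
#'   `"axon"` to restrict to that postsynaptic compartment.
#' @return `data.frame(target, partner, weight, fraction)`, sorted within
#'   target by decreasing weight (ties broken by partner id).
#' @export
input_budget <- function(synapses, targets, compartment = NULL) {
  check_columns(synapses, c("bodyid_pre", "bodyid_post", "weight"),
                "synapse table")
  stopifnot(all(synapses$weight >= 1))
  targets <- as.character(targets)
  s <- synapses[as.character(synapses$bodyid_post) %in% targets, ,
                drop = FALSE]
  if (!is.null(compartment)) {
    check_columns(synapses, "compartment_post", "synapse table")
    s <- s[s$compartment_post %in% compartment, , drop = FALSE]
  }
  out <- lapply(targets, function(tg) {
    st <- s[as.character(s$bodyid_post) == tg, , drop = FALSE]
    if (nrow(st) == 0L || sum(st$weight) == 0) {
      warning("target ", tg, " has zero inputs under the filter; ",
              "fractions undefined")
      return(NULL)
    }
    w <- tapply(st$weight, as.character(st$bodyid_pre), sum)
    df <- data.frame(target = tg, partner = names(w),
                     weight = as.numeric(w),
                     fraction = as.numeric(w) / sum(w))
    df[order(-df$weight, df$partner), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Median per-type (cluster) contribution to the input budget
#'
#' Maps each partner to a neuron type and reports, per target and type,
#' the median of the single-neuron budget fractions together with the
#' number of neurons in the cluster.
#'
#' @param budget Result of [input_budget()].
#' @param meta Neuron metadata with `bodyid` and `type_label` columns;
#'   every partner must be mapped.
#' @return `data.frame(target, type_label, n_neurons, median_fraction,
#'   total_weight)`, sorted within target by decreasing total weight.
#' @export
cluster_median_budget <- function(budget, meta) {
  check_columns(budget, c("target", "partner", "weight", "fraction"),
                "budget")
  check_columns(meta, c("bodyid", "type_label"), "neuron metadata")
  type <- meta$type_label[match(budget$partner, as.character(meta$bodyid))]
  if (anyNA(type)) {
    stop("partner(s) missing from metadata: ",
         paste(unique(budget$partner[is.na(type)]), collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(budget$target, type, drop = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    b <- budget[key == k, , drop = FALSE]
    data.frame(target = b$target[1],
               type_label = type[key == k][1],
               n_neurons = nrow(b),
               median_fraction = stats::median(b$fraction),
               total_weight = sum(b$weight))
  }))
  out <- out[order(out$target, -out$total_weight, out$type_label), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compartment restriction of a target's inputs and outputs
#'
#' Percentage of the targets' total input synapse weight landing on their
#' dendrites, and of their total output weight leaving from their axons;
#' unassigned compartments are reported separately. Used to check that a
#' neuron's connections are polarized (inputs dendritic, outputs axonal).
#'
#' @param synapses Synapse table with `bodyid_pre`, `bodyid_post`,
#'   `compartment_pre`, `compartment_post`, `weight`.
#' @param targets Target body ids (inputs/outputs pooled across them).
#' @return A list with `pct_inputs_dendritic`, `pct_outputs_axonal`,
#'   `pct_inputs_unassigned`, `pct_outputs_unassigned`,
#'   `total_input_weight`, `total_output_weight`.
#' @export
compartment_restriction <- function(synapses, targets) {
  check_columns(synapses, c("bodyid_pre", "bodyid_post", "compartment_pre",
                            "compartment_post", "weight"), "synapse table")
  targets <- as.character(targets)
  inp <- synapses[as.character(synapses$bodyid_post) %in% targets, ,
                  drop = FALSE]
  out <- synapses[as.character(synapses$bodyid_pre) %in% targets, ,
                  drop = FALSE]
  pct <- function(w, comp, which) {
    tot <- sum(w)
    if (tot == 0) return(NA_real_)
    100 * sum(w[!is.na(comp) & comp == which]) / tot
  }
  unass <- function(w, comp) {
    tot <- sum(w)
    if (tot == 0) return(NA_real_)
    100 * sum(w[is.na(comp) | comp == "unassigned"]) / tot
  }
  if (all(is.na(inp$compartment_post) |
          inp$compartment_post == "unassigned") &&
      all(is.na(out$compartment_pre) | out$compartment_pre == "unassigned")) {
    warning("all compartments unassigned; restriction undefined")
  }
  list(pct_inputs_dendritic = pct(inp$weight, inp$compartment_post,
                                  "dendrite"),
       pct_outputs_axonal = pct(out$weight, out$compartment_pre, "axon"),
       pct_inputs_unassigned = unass(inp$weight, inp$compartment_post),
       pct_outputs_unassigned = unass(out$weight, out$compartment_pre),
       total_input_weight = sum(inp$weight),
       total_output_weight = sum(out$weight))
}

#' Rule-based neuron classification
#'
#' Classifies each neuron in the metadata as a putative olfactory
#' projection neuron, lateral-horn-associated, or other:
#' \itemize{
#'   \item putative olfactory PN: receives inputs (has dendrites) in the
#'     antennal lobe;
#'   \item LH-associated: has dendritic projections inside the lateral
#'     horn, receives at least one synapse from a listed olfactory PN, and
#'     has output (axonal) neuropils outside the LH;
#'   \item other: neither.
#' }
#' The PN rule takes precedence. Neurons with missing neuropil annotation
#' are unclassifiable (`NA`) and flagged.
#'
#' @param meta Neuron metadata with `bodyid`, `dendritic_neuropils` and
#'   `axonal_neuropils` columns; neuropil sets are semicolon-separated
#'   strings (e.g. `"LH;SLP"`), empty string = none, `NA` = unannotated.
#' @param synapses Synapse table (used for the PN-input requirement).
#' @param olfactory_pn_ids Body ids of known olfactory projection neurons.
#' @param lh_label,al_label Neuropil labels for the lateral horn and
#'   antennal lobe.
#' @return `data.frame(bodyid, class)` with class in
#'   `{"putative olfactory PN", "LH-associated", "other", NA}`.
#' @export
classify_neuron <- function(meta, synapses, olfactory_pn_ids,
                            lh_label = "LH", al_label = "AL") {
  check_columns(meta, c("bodyid", "dendritic_neuropils", "axonal_neuropils"),
                "neuron metadata")
  check_columns(synapses, c("bodyid_pre", "bodyid_post", "weight"),
                "synapse table")
  olfactory_pn_ids <- as.character(olfactory_pn_ids)
  split_np <- function(s) {
    if (is.na(s)) return(NULL)  # unannotated
    strsplit(s, ";", fixed = TRUE)[[1]]
  }
  cls <- vapply(seq_len(nrow(meta)), function(i) {
    dend <- split_np(meta$dendritic_neuropils[i])
    axon <- split_np(meta$axonal_neuropils[i])
    if (is.null(dend) || is.null(axon)) return(NA_character_)
    if (al_label %in% dend) return("putative olfactory PN")
    id <- as.character(meta$bodyid[i])
    pn_in <- synapses$weight[as.character(synapses$bodyid_post) == id &
                             as.character(synapses$bodyid_pre) %in%
                               olfactory_pn_ids]
    if (lh_label %in% dend && sum(pn_in) >= 1 &&
        length(setdiff(axon, lh_label)) > 0L) {
      return("LH-associated")
    }
    "other"
  }, character(1))
  if (anyNA(cls)) warning("neuron(s) with missing neuropil annotation ",
                          "are unclassifiable")
  data.frame(bodyid = meta$bodyid, class = cls)
}

#' Top upstream partners by synaptic connection weight
#'
#' Ranks a budget report by total synapse weight, descending, with ties
#' broken by partner id for determinism, and returns the top `n` rows per
#' target.
#'
#' @param budget Result of [input_budget()] (or the per-type table from
#'   [cluster_median_budget()]; any table with a `weight` column and a
#'   partner identifier column).
#' @param n Number of partners to keep per target.
#' @param id_col Name of the identifier column used for tie-breaking.
#' @return The ranked, truncated table.
#' @export
top_partners <- function(budget, n = 30, id_col = "partner") {
  check_columns(budget, c("target", "weight", id_col), "budget")
  if (nrow(budget) == 0L) stop("budget report is empty")
  out <- do.call(rbind, lapply(unique(budget$target), function(tg) {
    b <- budget[budget$target == tg, , drop = FALSE]
    b <- b[order(-b$weight, b[[id_col]]), , drop = FALSE]
    utils::head(b, n)
  }))
  rownames(out) <- NULL
  out
}
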