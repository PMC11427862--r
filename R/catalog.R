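#' Bundled microintervention catalog
#'
#' The deployed system offered brief (under five minute) stress-reduction
#' microinterventions translated from cognitive behavioral therapy and
#' dialectical behavior therapy components, organized along three axes:
#' the function served (`distract` = get my mind off work, `calm` = feel
#' calm and present, `address` = think through my stress), the delivery
#' modality (`video`, `prompt`, or a turn-taking chatbot `conversation`),
#' and the intended location (`at_desk`, `inside` but away from the desk,
#' or `outside`). The catalog holds 18 interventions per functional
#' category. Intervention content text is out of scope; items are
#' identified by id and their three attributes.
#'
#' @return Data frame with columns `intervention_id`, `category`,
#'   `modality`, `location` (54 rows, 18 per category).
#' @export
intervention_catalog <- function() {
  categories <- c("distract", "calm", "address")
  # Per category: mostly prompt-based items, a few videos, two chatbot
  # conversations; mostly performable at the desk. A fixed permutation keeps
  # modality and location from being confounded within a category.
  modality <- rep(c("prompt", "video", "conversation"), c(12, 4, 2))
  location <- rep(c("at_desk", "inside", "outside"), c(14, 3, 1))[
    c(1, 5, 9, 15, 2, 6, 10, 16, 3, 7, 11, 17, 4, 8, 12, 18, 13, 14)]
  do.call(rbind, lapply(categories, function(cat) {
    data.frame(
      intervention_id = sprintf("%s_%02d", cat, seq_len(18)),
      category = cat,
      modality = modality,
      location = location,
      stringsAsFactors = FALSE
    )
  }))
}

#' Randomly select an intervention within a category
#'
#' The system draws uniformly among the category's catalog items not yet
#' served to this participant; once all 18 have been served, the served set
#' for that category resets and all items become eligible again.
#'
#' @param category One of `"distract"`, `"calm"`, `"address"`.
#' @param served Character vector of intervention ids already served to the
#'   participant.
#' @param catalog Catalog data frame, see [intervention_catalog()].
#' @return List with `item` (one catalog row) and `served` (updated vector).
#' @export
select_intervention <- function(category, served = character(),
                                catalog = intervention_catalog()) {
  if (!category %in% catalog$category) {
    stop("unknown intervention category: ", category)
  }
  pool <- catalog[catalog$category == category, , drop = FALSE]
  if (nrow(pool) == 0) stop("empty intervention catalog")
  available <- setdiff(pool$intervention_id, served)
  if (length(available) == 0) {
    # exhausted: reset the served set for this category
    served <- setdiff(served, pool$intervention_id)
    available <- pool$intervention_id
  }
  pick <- if (length(available) == 1) available else sample(available, 1)
  list(item = pool[pool$intervention_id == pick, , drop = FALSE],
       served = c(served, pick))
}
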