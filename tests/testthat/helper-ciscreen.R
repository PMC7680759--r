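## Build a screen_data object from bare (hatched, laid) pairs.
wells_df <- function(hatched, laid, condition = "ci-control",
                     plate_id = "P1", treatment = NA_character_) {
  data.frame(
    plate_id = plate_id,
    well_id = paste0("W", seq_along(hatched)),
    condition = condition,
    treatment = treatment,
    eggs_laid = laid,
    eggs_hatched = hatched,
    stringsAsFactors = FALSE
  )
}

make_screen <- function(hatched, laid, condition = "ci-control", ...) {
  screen_data(wells_df(hatched, laid, condition, ...))
}

## Random well table over several plates/conditions, for property checks.
random_dataset <- function(n_wells = 30L) {
  laid <- sample(1:300, n_wells, replace = TRUE)
  data.frame(
    plate_id = sample(paste0("P", 1:3), n_wells, replace = TRUE),
    well_id = paste0("W", seq_len(n_wells)),
    condition = sample(ci_conditions(), n_wells, replace = TRUE),
    eggs_laid = laid,
    eggs_hatched = vapply(laid, function(n) sample(0:n, 1L), integer(1)),
    stringsAsFactors = FALSE
  )
}

## A two-window dose record with specified fractional losses per stage.
dose_record <- function(early_loss = c(0, 0, 0), late_loss = c(0, 0, 0),
                        control = c(100, 80, 60)) {
  stages <- c("eggs", "larvae", "pupae")
  data.frame(
    window = rep(c("early", "late"), each = 3L),
    stage = rep(stages, 2L),
    count = round(c(control * (1 - early_loss), control * (1 - late_loss))),
    control_count = rep(control, 2L)
  )
}
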