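# Speed configuration: per-class road speeds, walking/bus/train defaults,
# and the alias map between narrative road-class vocabulary and the class
# table used for speed lookup.

#' Travel-speed configuration
#'
#' Holds the per-class road speed table, the constant walking speed, default
#' bus and train speeds, and an alias map translating alternative road-class
#' names (e.g. "primary highway") onto the speed table's classes.
#'
#' @param classes Named numeric vector of km/h by road class. The default is
#'   the urban speed table Collector 50, Major 65, Expressway 80, Alley 15.
#' @param walking_kmh Constant walking speed in km/h (default 4.8, a standard
#'   municipal average walking speed).
#' @param bus_default_kmh Speed for bus routes whose class is missing or
#'   unknown (default 40).
#' @param train_kmh Light-rail speed (default 45).
#' @param aliases Named character vector mapping alternative class names to
#'   names of `classes`.
#' @return An object of class `speed_map`.
#' @examples
#' sm <- speed_map()
#' resolve_speed(sm, "Collector", "road")
#' @export
speed_map <- function(classes = c(Collector = 50, Major = 65,
                                  Expressway = 80, Alley = 15),
                      walking_kmh = 4.8,
                      bus_default_kmh = 40,
                      train_kmh = 45,
                      aliases = c("primary highway" = "Expressway",
                                  "secondary highway" = "Major",
                                  "major road" = "Major",
                                  "local road" = "Collector")) {
  if (is.null(names(classes)) || any(!nzchar(names(classes))))
    stopf("`classes` must be a named vector")
  if (any(classes <= 0)) stopf("all class speeds must be positive")
  check_number(walking_kmh, "walking_kmh", 0, strict = TRUE)
  check_number(bus_default_kmh, "bus_default_kmh", 0, strict = TRUE)
  check_number(train_kmh, "train_kmh", 0, strict = TRUE)
  structure(list(classes = classes, walking_kmh = walking_kmh,
                 bus_default_kmh = bus_default_kmh, train_kmh = train_kmh,
                 aliases = aliases),
            class = "speed_map")
}

#' Resolve a speed for one class/mode combination
#'
#' @param speeds A [speed_map()].
#' @param class_label Road or route class, possibly `NA`.
#' @param mode Segment mode (see [geo_segments()]).
#' @param strict For `"road"`/`"bus"`: error on an unknown class instead of
#'   falling back (roads always error; buses fall back to
#'   `bus_default_kmh` unless `strict`).
#' @return Speed in km/h.
#' @export
resolve_speed <- function(speeds, class_label, mode, strict = FALSE) {
  stopifnot(inherits(speeds, "speed_map"))
  lookup_class <- function(cl) {
    if (is.na(cl)) return(NA_real_)
    if (cl %in% names(speeds$classes)) return(unname(speeds$classes[[cl]]))
    if (cl %in% names(speeds$aliases)) {
      tgt <- speeds$aliases[[cl]]
      if (tgt %in% names(speeds$classes))
        return(unname(speeds$classes[[tgt]]))
    }
    NA_real_
  }
  switch(mode,
    road = {
      s <- lookup_class(class_label)
      if (is.na(s))
        stopf("no speed configured for road class '%s'", class_label)
      s
    },
    sidewalk = , trail = , pathway = , crosswalk = , link = speeds$walking_kmh,
    bus = {
      s <- lookup_class(class_label)
      if (is.na(s)) {
        if (strict) stopf("no speed configured for bus class '%s'", class_label)
        speeds$bus_default_kmh
      } else s
    },
    train = speeds$train_kmh,
    stopf("unknown mode '%s'", mode)
  )
}

# Fill the speed_kmh column of a segment layer wherever it is NA.
resolve_segment_speeds <- function(segments, speeds) {
  miss <- which(is.na(segments$speed_kmh))
  for (i in miss) {
    segments$speed_kmh[i] <- resolve_speed(speeds, segments$class_label[i],
                                           segments$mode[i])
  }
  segments
}
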