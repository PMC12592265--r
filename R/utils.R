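# Angle helpers. Convention throughout: degrees at the interface, +y up,
# angles measured counterclockwise from +x, wrapped to (-180, 180].

#' Wrap angles to (-180, 180] degrees
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @export
wrap180 <- function(a) {
  r <- a %% 360
  over <- !is.na(r) & r > 180
  r[over] <- r[over] - 360
  r
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_insufficient <- function(msg) {
  stop(structure(class = c("antnav_insufficient_data", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_format <- function(msg) {
  stop(structure(class = c("antnav_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
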