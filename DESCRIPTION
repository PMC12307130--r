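Package: roostradar
Title: Quantifying Swallow and Martin Roosts from Weather Radar Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Converts polar weather-radar reflectivity volumes into bird
    counts for annotated roost-dispersal bounding boxes. Implements the
    reflectivity-to-animal-density conversion (dBZ to linear Z to eta,
    divided by a per-bird radar cross section), conical-frustum sampling
    volumes with a Monte Carlo correction for azimuthal beam overlap,
    quantile-based ground-clutter masking, heuristic detection-to-track
    linking with peak counts, day-level sampling classification with
    presence and true-zero calendars, mean-shift clustering of roost
    locations, radar sensitivity profiles, and two-region comparison
    statistics. Includes a synthetic polar-scene generator that injects
    ring-shaped roost dispersals of known bird number, static ground
    clutter, and precipitation, so the full pipeline can be exercised and
    validated without access to a proprietary radar archive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
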