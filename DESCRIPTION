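Package: bilayr
Title: Analysis of Planar Lipid-Bilayer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for planar lipid-bilayer molecular trajectories:
    leaflet assignment, membrane thickness and area per lipid, coarse-grained
    (P2) and deuterium (S_CD) order parameters, electron/charge density and
    dipole-potential profiles, radial distribution functions, guest-lipid
    contact-recurrence fingerprints, lateral diffusion by the Einstein
    relation, and sterol/lipid flip-flop detection with a residency criterion.
    Also validates coarse-grained mappings by comparing bond, angle and
    dihedral distributions of a centre-of-mass-mapped atomistic trajectory
    against a coarse-grained one. Ships a synthetic bilayer generator with
    fully known ground truth (geometry, tilt distribution, lateral diffusion
    coefficient, scripted leaflet translocations) so every analysis can be
    tested without a molecular-dynamics engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
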