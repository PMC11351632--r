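Package: oviductsim
Title: Reduced-Order Simulation of Gamete Transport Through the Human Fallopian Tube
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds parametric three-dimensional models of the human fallopian
    tube (normal and with tubal endometriosis lesions) for women in their 20s,
    30s and 40s, computes the peristalsis-ciliary mucus flow inside them with a
    lubrication-theory approximation, propels sperm agents by a
    resistive-force-theory flagellar beat driven by dynein sliding forces,
    advects oocyte agents as confined Stokes spheres with corona radiata
    shedding, and tracks thousands of agents for up to 80 simulated hours to
    estimate the percentage of sperm reaching the ampullary fertilization site
    and of oocytes reaching the uterine cavity, together with the reduction of
    those percentages caused by endometriosis lesions and by aging.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
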