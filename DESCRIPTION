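Package: somgesture
Title: Facial Gesture Recognition from EEG Band Power with a SOM-Hebb Classifier
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognises facial gestures (eye closure, eye widening, left/right
    teeth clenching and their combinations) from 16-channel EEG by exploiting
    the muscle and eye artifacts they leave in the alpha, beta and theta bands.
    Provides a seeded synthetic EEG generator reproducing the class-conditional
    band-power signatures of the gestures, Welch band-power feature extraction
    (48-dimensional alpha/beta/theta per-channel vectors), and a SOM-Hebb
    classifier: an unsupervised self-organizing map trained by competitive
    learning, labeled per neuron by supervised Hebbian win counting, with
    never-winning neurons disabled during recall. Includes evaluation tools
    (confusion matrices, accuracy) and a batch experiment runner mirroring the
    offline-training / recall protocol.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    graphics,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
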