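# Detector active-volume library (dimensions in mm).
#
# Entries marked `approximate: true` encode dimensions reconstructed from
# published constraints (nominal active volume, quoted active length and
# length-to-diameter ratios) rather than copied from a manufacturer data
# sheet; override any entry by editing this file or pointing
# load_detector_library() at your own copy. Chambers are a cylindrical gas
# cavity plus a hemispherical cap on top minus a coaxial central electrode;
# the long axis is z and the placement convention puts the centroid of the
# active volume at the field centre.
- name: Semiflex T31010
  type: ionization chamber
  shape: chamber
  cavity_radius: 2.75
  cavity_length: 3.548
  cap: true
  electrode_radius: 0.55
  electrode_length: 3.0
  nominal_volume_mm3: 125
  approximate: true
- name: Semiflex 3D T31021
  type: ionization chamber
  shape: chamber
  cavity_radius: 2.4
  cavity_length: 2.3239
  cap: true
  electrode_radius: 0.4
  electrode_length: 2.0
  nominal_volume_mm3: 70
  approximate: true
- name: PinPoint T31014
  type: ionization chamber
  shape: chamber
  # quoted active length 5 mm with length-to-diameter ratio 2.5
  cavity_radius: 1.0
  cavity_length: 4.0
  cap: true
  electrode_radius: 0.15
  electrode_length: 3.0
  nominal_volume_mm3: 15
  approximate: true
- name: PinPoint 3D T31022
  type: ionization chamber
  shape: chamber
  # length-to-diameter ratio 1.23
  cavity_radius: 1.35
  cavity_length: 1.971
  cap: true
  electrode_radius: 0.45
  electrode_length: 1.5
  nominal_volume_mm3: 16
  approximate: true
- name: Diode P T60016
  type: semiconductor
  shape: disk
  radius: 0.565
  thickness: 0.03
  nominal_volume_mm3: 0.030
  approximate: true
- name: Diode E T60017
  type: semiconductor
  shape: disk
  # identical active volume to Diode P; the two differ only in shielding
  radius: 0.565
  thickness: 0.03
  nominal_volume_mm3: 0.030
  approximate: true
- name: microDiamond T60019
  type: diamond
  shape: disk
  # very thin (1 um) disk of large 2.2 mm diameter
  radius: 1.1
  thickness: 0.001
  nominal_volume_mm3: 0.004
  approximate: false
- name: RAZOR diode
  type: semiconductor
  shape: disk
  radius: 0.3
  thickness: 0.0707
  nominal_volume_mm3: 0.020
  approximate: true
- name: EFD 3G-pSi
  type: semiconductor
  shape: disk
  radius: 1.0
  thickness: 0.0509
  nominal_volume_mm3: 0.160
  approximate: true
- name: EDGE detector
  type: semiconductor
  shape: box
  dx: 0.8
  dy: 0.8
  dz: 0.03
  nominal_volume_mm3: 0.020
  approximate: true
- name: RAZOR chamber
  type: ionization chamber
  shape: chamber
  cavity_radius: 1.3
  cavity_length: 1.0893
  cap: true
  electrode_radius: 0.35
  electrode_length: 1.0
  nominal_volume_mm3: 10
  approximate: true
- name: IBA CC04
  type: ionization chamber
  shape: chamber
  # quoted active length 3.6 mm with length-to-diameter ratio 0.9
  cavity_radius: 2.0
  cavity_length: 1.6
  cap: true
  electrode_radius: 0.35
  electrode_length: 1.0
  nominal_volume_mm3: 40
  approximate: true
- name: Exradin W2 1x1
  type: plastic scintillator
  shape: disk
  # 1 mm diameter x 1 mm long scintillating fibre
  radius: 0.5
  thickness: 1.0
  nominal_volume_mm3: 0.785
  approximate: false
- name: Exradin W2 1x3
  type: plastic scintillator
  shape: disk
  radius: 0.5
  thickness: 3.0
  nominal_volume_mm3: 2.356
  approximate: false
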