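# Reference material registry for the thin-wall tube-law utilities.
# Moduli: vein 0.445 MPa (cephalic-vein stress-strain behaviour linearised
# over the 30-60 mmHg post-operative working range), ePTFE 55 MPa
# (Catanese et al.), electrospun polyurethane 1.5 MPa (Montini-Ballarin
# et al.). Vein wall thickness is 10% of the zero-pressure radius; the graft
# wall is 0.63 mm. Zero-pressure diameters: vein 7.14 mm (reconstructed from
# pre-operative ultrasound), graft 6 mm.
vein:
  name: vein
  youngs_modulus_Pa: 445000.0
  thickness_ratio: 0.1
  zero_pressure_diameter_m: 0.00714
ePTFE:
  name: ePTFE
  youngs_modulus_Pa: 55000000.0
  wall_thickness_m: 0.00063
  zero_pressure_diameter_m: 0.006
ePU:
  name: ePU
  youngs_modulus_Pa: 1500000.0
  wall_thickness_m: 0.00063
  zero_pressure_diameter_m: 0.006
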