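"""Build inst/extdata/element_properties.csv (Z=1..86, 15 numeric properties).

Derivable columns (weight, radii, valence electrons, group/period/block) come
from rdkit's periodic table / Z arithmetic; physical properties are standard
reference values (CRC-style), NA where no stable/accepted value exists.
"""
import csv
from rdkit import Chem

pt = Chem.GetPeriodicTable()

SYM = [pt.GetElementSymbol(z) for z in range(1, 87)]

def period(z):
    for p, hi in enumerate([2, 10, 18, 36, 54, 86], start=1):
        if z <= hi:
            return p

def group_block(z):
    # returns (group 1..18 or NA for lanthanides, block ordinal s=0,p=1,d=2,f=3)
    if z in (1,): return 1, 0
    if z == 2: return 18, 0
    offs = {3: 2, 11: 10, 19: 18, 37: 36, 55: 54}
    for start in (3, 11):
        if start <= z <= start + 7:
            i = z - (start - 1)  # 1..8
            return (i if i <= 2 else i + 10), 0 if i <= 2 else 1
    for start in (19, 37):
        if start <= z <= start + 17:
            i = z - (start - 1)  # 1..18
            if i <= 2: return i, 0
            if i <= 12: return i, 2
            return i, 1
    if 55 <= z <= 86:
        i = z - 54  # 1..32
        if i <= 2: return i, 0
        if z <= 71: return float('nan'), 3        # lanthanides: no group
        if z <= 80: return z - 68, 2
        return z - 68, 1
    raise ValueError(z)

def valence_electrons(z):
    try:
        return pt.GetNOuterElecs(z)
    except Exception:
        return float('nan')

# Pauling electronegativity
EN_PAULING = {
 'H':2.20,'Li':0.98,'Be':1.57,'B':2.04,'C':2.55,'N':3.04,'O':3.44,'F':3.98,
 'Na':0.93,'Mg':1.31,'Al':1.61,'Si':1.90,'P':2.19,'S':2.58,'Cl':3.16,
 'K':0.82,'Ca':1.00,'Sc':1.36,'Ti':1.54,'V':1.63,'Cr':1.66,'Mn':1.55,
 'Fe':1.83,'Co':1.88,'Ni':1.91,'Cu':1.90,'Zn':1.65,'Ga':1.81,'Ge':2.01,
 'As':2.18,'Se':2.55,'Br':2.96,'Kr':3.00,'Rb':0.82,'Sr':0.95,'Y':1.22,
 'Zr':1.33,'Nb':1.60,'Mo':2.16,'Tc':1.90,'Ru':2.20,'Rh':2.28,'Pd':2.20,
 'Ag':1.93,'Cd':1.69,'In':1.78,'Sn':1.96,'Sb':2.05,'Te':2.10,'I':2.66,
 'Xe':2.60,'Cs':0.79,'Ba':0.89,'La':1.10,'Ce':1.12,'Pr':1.13,'Nd':1.14,
 'Sm':1.17,'Gd':1.20,'Tb':1.10,'Dy':1.22,'Ho':1.23,'Er':1.24,'Tm':1.25,
 'Lu':1.27,'Hf':1.30,'Ta':1.50,'W':2.36,'Re':1.90,'Os':2.20,'Ir':2.20,
 'Pt':2.28,'Au':2.54,'Hg':2.00,'Tl':1.62,'Pb':2.33,'Bi':2.02,'Po':2.00,
 'At':2.20,'Rn':2.20,
}
# Allen electronegativity (configuration energies), main group mostly
EN_ALLEN = {
 'H':2.300,'He':4.160,'Li':0.912,'Be':1.576,'B':2.051,'C':2.544,'N':3.066,
 'O':3.610,'F':4.193,'Ne':4.787,'Na':0.869,'Mg':1.293,'Al':1.613,'Si':1.916,
 'P':2.253,'S':2.589,'Cl':2.869,'Ar':3.242,'K':0.734,'Ca':1.034,'Sc':1.19,
 'Ti':1.38,'V':1.53,'Cr':1.65,'Mn':1.75,'Fe':1.80,'Co':1.84,'Ni':1.88,
 'Cu':1.85,'Zn':1.59,'Ga':1.756,'Ge':1.994,'As':2.211,'Se':2.424,'Br':2.685,
 'Kr':2.966,'Rb':0.706,'Sr':0.963,'In':1.656,'Sn':1.824,'Sb':1.984,
 'Te':2.158,'I':2.359,'Xe':2.582,'Cs':0.659,'Ba':0.881,'Tl':1.789,
 'Pb':1.854,'Bi':2.01,'Po':2.19,'At':2.39,'Rn':2.60,
}
# Electron affinity, eV (NA where anion unbound / not measured)
EA = {
 'H':0.754,'Li':0.618,'B':0.280,'C':1.263,'N':-0.07,'O':1.461,'F':3.401,
 'Na':0.548,'Al':0.433,'Si':1.390,'P':0.746,'S':2.077,'Cl':3.613,
 'K':0.501,'Ca':0.025,'Sc':0.188,'Ti':0.079,'V':0.525,'Cr':0.666,
 'Fe':0.151,'Co':0.662,'Ni':1.156,'Cu':1.235,'Ga':0.43,'Ge':1.233,
 'As':0.804,'Se':2.021,'Br':3.364,'Rb':0.486,'Sr':0.048,'Y':0.307,
 'Zr':0.426,'Nb':0.893,'Mo':0.748,'Tc':0.55,'Ru':1.05,'Rh':1.137,
 'Pd':0.562,'Ag':1.302,'In':0.3,'Sn':1.112,'Sb':1.046,'Te':1.971,
 'I':3.059,'Cs':0.472,'Ba':0.145,'La':0.47,'Ce':0.65,'Hf':0.017,
 'Ta':0.322,'W':0.815,'Re':0.15,'Os':1.1,'Ir':1.565,'Pt':2.128,
 'Au':2.309,'Tl':0.377,'Pb':0.356,'Bi':0.942,'Po':1.9,'At':2.8,
}
# First ionization energy, eV
IE = {
 'H':13.598,'He':24.587,'Li':5.392,'Be':9.323,'B':8.298,'C':11.260,
 'N':14.534,'O':13.618,'F':17.423,'Ne':21.565,'Na':5.139,'Mg':7.646,
 'Al':5.986,'Si':8.152,'P':10.487,'S':10.360,'Cl':12.968,'Ar':15.760,
 'K':4.341,'Ca':6.113,'Sc':6.561,'Ti':6.828,'V':6.746,'Cr':6.767,
 'Mn':7.434,'Fe':7.902,'Co':7.881,'Ni':7.640,'Cu':7.726,'Zn':9.394,
 'Ga':5.999,'Ge':7.899,'As':9.789,'Se':9.752,'Br':11.814,'Kr':14.000,
 'Rb':4.177,'Sr':5.695,'Y':6.217,'Zr':6.634,'Nb':6.759,'Mo':7.092,
 'Tc':7.28,'Ru':7.361,'Rh':7.459,'Pd':8.337,'Ag':7.576,'Cd':8.994,
 'In':5.786,'Sn':7.344,'Sb':8.608,'Te':9.010,'I':10.451,'Xe':12.130,
 'Cs':3.894,'Ba':5.212,'La':5.577,'Ce':5.539,'Pr':5.473,'Nd':5.525,
 'Pm':5.582,'Sm':5.644,'Eu':5.670,'Gd':6.150,'Tb':5.864,'Dy':5.939,
 'Ho':6.022,'Er':6.108,'Tm':6.184,'Yb':6.254,'Lu':5.426,'Hf':6.825,
 'Ta':7.550,'W':7.864,'Re':7.834,'Os':8.438,'Ir':8.967,'Pt':8.959,
 'Au':9.226,'Hg':10.437,'Tl':6.108,'Pb':7.417,'Bi':7.286,'Po':8.414,
 'At':9.318,'Rn':10.748,
}
# Melting / boiling points (K) and density (g/cm3)
MP = {
 'H':13.99,'He':0.95,'Li':453.7,'Be':1560,'B':2349,'C':3823,'N':63.15,
 'O':54.36,'F':53.5,'Ne':24.56,'Na':370.9,'Mg':923,'Al':933.5,'Si':1687,
 'P':317.3,'S':388.4,'Cl':171.6,'Ar':83.8,'K':336.5,'Ca':1115,'Sc':1814,
 'Ti':1941,'V':2183,'Cr':2180,'Mn':1519,'Fe':1811,'Co':1768,'Ni':1728,
 'Cu':1357.8,'Zn':692.7,'Ga':302.9,'Ge':1211.4,'As':1090,'Se':494,
 'Br':265.8,'Kr':115.8,'Rb':312.5,'Sr':1050,'Y':1799,'Zr':2128,'Nb':2750,
 'Mo':2896,'Tc':2430,'Ru':2607,'Rh':2237,'Pd':1828,'Ag':1234.9,'Cd':594.2,
 'In':429.8,'Sn':505.1,'Sb':903.8,'Te':722.7,'I':386.9,'Xe':161.4,
 'Cs':301.6,'Ba':1000,'La':1193,'Ce':1068,'Pr':1208,'Nd':1297,'Pm':1315,
 'Sm':1345,'Eu':1099,'Gd':1585,'Tb':1629,'Dy':1680,'Ho':1734,'Er':1802,
 'Tm':1818,'Yb':1097,'Lu':1925,'Hf':2506,'Ta':3290,'W':3695,'Re':3459,
 'Os':3306,'Ir':2719,'Pt':2041.4,'Au':1337.3,'Hg':234.3,'Tl':577,
 'Pb':600.6,'Bi':544.6,'Po':527,'At':575,'Rn':202,
}
BP = {
 'H':20.27,'He':4.22,'Li':1560,'Be':2742,'B':4200,'C':4300,'N':77.36,
 'O':90.2,'F':85.0,'Ne':27.1,'Na':1156,'Mg':1363,'Al':2792,'Si':3538,
 'P':553.7,'S':717.8,'Cl':239.1,'Ar':87.3,'K':1032,'Ca':1757,'Sc':3109,
 'Ti':3560,'V':3680,'Cr':2944,'Mn':2334,'Fe':3134,'Co':3200,'Ni':3186,
 'Cu':2835,'Zn':1180,'Ga':2477,'Ge':3106,'As':887,'Se':958,'Br':332,
 'Kr':119.9,'Rb':961,'Sr':1655,'Y':3609,'Zr':4682,'Nb':5017,'Mo':4912,
 'Tc':4538,'Ru':4423,'Rh':3968,'Pd':3236,'Ag':2435,'Cd':1040,'In':2345,
 'Sn':2875,'Sb':1860,'Te':1261,'I':457.6,'Xe':165.1,'Cs':944,'Ba':2170,
 'La':3737,'Ce':3716,'Pr':3793,'Nd':3347,'Pm':3273,'Sm':2067,'Eu':1802,
 'Gd':3546,'Tb':3503,'Dy':2840,'Ho':2993,'Er':3141,'Tm':2223,'Yb':1469,
 'Lu':3675,'Hf':4876,'Ta':5731,'W':5828,'Re':5869,'Os':5285,'Ir':4701,
 'Pt':4098,'Au':3129,'Hg':629.9,'Tl':1746,'Pb':2022,'Bi':1837,'Po':1235,
 'At':610,'Rn':211.5,
}
DENS = {
 'H':8.99e-5,'He':1.785e-4,'Li':0.534,'Be':1.85,'B':2.34,'C':2.267,
 'N':1.251e-3,'O':1.429e-3,'F':1.696e-3,'Ne':9.0e-4,'Na':0.971,'Mg':1.738,
 'Al':2.698,'Si':2.329,'P':1.82,'S':2.067,'Cl':3.214e-3,'Ar':1.784e-3,
 'K':0.862,'Ca':1.54,'Sc':2.989,'Ti':4.506,'V':6.0,'Cr':7.19,'Mn':7.21,
 'Fe':7.874,'Co':8.90,'Ni':8.908,'Cu':8.96,'Zn':7.14,'Ga':5.91,'Ge':5.323,
 'As':5.776,'Se':4.809,'Br':3.122,'Kr':3.749e-3,'Rb':1.532,'Sr':2.64,
 'Y':4.469,'Zr':6.506,'Nb':8.57,'Mo':10.22,'Tc':11.5,'Ru':12.37,
 'Rh':12.41,'Pd':12.02,'Ag':10.49,'Cd':8.65,'In':7.31,'Sn':7.287,
 'Sb':6.685,'Te':6.232,'I':4.93,'Xe':5.894e-3,'Cs':1.873,'Ba':3.594,
 'La':6.145,'Ce':6.77,'Pr':6.773,'Nd':7.007,'Pm':7.26,'Sm':7.52,
 'Eu':5.243,'Gd':7.895,'Tb':8.229,'Dy':8.55,'Ho':8.795,'Er':9.066,
 'Tm':9.321,'Yb':6.965,'Lu':9.84,'Hf':13.31,'Ta':16.69,'W':19.25,
 'Re':21.02,'Os':22.59,'Ir':22.56,'Pt':21.45,'Au':19.3,'Hg':13.534,
 'Pb':11.34,'Tl':11.85,'Bi':9.78,'Po':9.196,'Rn':9.73e-3,
}

rows = []
for z in range(1, 87):
    s = SYM[z - 1]
    g, b = group_block(z)
    w = pt.GetAtomicWeight(z)
    dens = DENS.get(s, float('nan'))
    vol = w / dens if dens == dens and dens > 0 else float('nan')
    rows.append(dict(
        z=z, symbol=s,
        atomic_weight=round(w, 4),
        group=g, period=period(z), block=b,
        valence_electrons=valence_electrons(z),
        covalent_radius=round(pt.GetRcovalent(z), 3),
        vdw_radius=round(pt.GetRvdw(z), 3),
        en_pauling=EN_PAULING.get(s, float('nan')),
        en_allen=EN_ALLEN.get(s, float('nan')),
        electron_affinity=EA.get(s, float('nan')),
        ionization_energy=IE.get(s, float('nan')),
        melting_point=MP.get(s, float('nan')),
        boiling_point=BP.get(s, float('nan')),
        density=dens,
        atomic_volume=round(vol, 3) if vol == vol else float('nan'),
    ))

with open('/root/pkg/inst/extdata/element_properties.csv', 'w', newline='') as f:
    w = csv.DictWriter(f, fieldnames=list(rows[0].keys()))
    w.writeheader()
    for r in rows:
        w.writerow({k: ('' if v != v else v) if isinstance(v, float) else v
                    for k, v in r.items()})
print("wrote", len(rows), "rows")
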