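# Eleven pelargonidin-derivative peaks from HPLC-ESI-MS/MS of orange
# gentian petals: precursor [M]+ and fragment m/z as published. Fragment
# intensities were not published; all are set to 100 (annotation is
# intensity-free).
BEGIN IONS
TITLE=peak1
PEPMASS=741.221800
CHARGE=1+
RTINSECONDS=412.800
579.169920 100
433.112370 100
271.059660 100
END IONS
BEGIN IONS
TITLE=peak2
PEPMASS=595.165160
CHARGE=1+
RTINSECONDS=516.600
433.112730 100
271.059720 100
END IONS
BEGIN IONS
TITLE=peak3
PEPMASS=579.170780
CHARGE=1+
RTINSECONDS=669.000
433.113070 100
271.059810 100
146.057900 100
END IONS
BEGIN IONS
TITLE=peak4
PEPMASS=433.112030
CHARGE=1+
RTINSECONDS=751.800
271.059690 100
END IONS
BEGIN IONS
TITLE=peak5
PEPMASS=1094.293580
CHARGE=1+
RTINSECONDS=763.800
932.238830 100
771.213680 100
433.112730 100
271.060000 100
END IONS
BEGIN IONS
TITLE=peak6
PEPMASS=1079.302840
CHARGE=1+
RTINSECONDS=784.200
932.238710 100
771.213680 100
433.112730 100
271.059720 100
END IONS
BEGIN IONS
TITLE=peak7
PEPMASS=843.220950
CHARGE=1+
RTINSECONDS=832.200
681.166750 100
595.163330 100
519.114560 100
433.113920 100
271.060330 100
END IONS
BEGIN IONS
TITLE=peak8
PEPMASS=827.219360
CHARGE=1+
RTINSECONDS=856.800
579.170040 100
519.112300 100
271.059720 100
END IONS
BEGIN IONS
TITLE=peak9
PEPMASS=681.165650
CHARGE=1+
RTINSECONDS=896.400
519.112980 100
433.112430 100
271.059630 100
END IONS
BEGIN IONS
TITLE=peak10
PEPMASS=517.097550
CHARGE=1+
RTINSECONDS=913.200
433.113070 100
271.060730 100
END IONS
BEGIN IONS
TITLE=peak11
PEPMASS=579.150120
CHARGE=1+
RTINSECONDS=939.600
433.113070 100
271.059570 100
END IONS
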