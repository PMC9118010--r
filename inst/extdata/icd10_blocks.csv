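block_id,included
A00-A09,TRUE
A15-A19,TRUE
A20-A28,TRUE
A30-A49,TRUE
A50-A64,TRUE
A65-A69,TRUE
A70-A74,TRUE
A75-A79,TRUE
A80-A89,TRUE
A90-A99,TRUE
B00-B09,TRUE
B15-B19,TRUE
B20-B24,TRUE
B25-B34,TRUE
B35-B49,TRUE
B50-B64,TRUE
B65-B83,TRUE
B85-B89,TRUE
B90-B94,TRUE
B95-B98,TRUE
B99-B99,TRUE
C00-C14,TRUE
C15-C26,TRUE
C30-C39,TRUE
C40-C41,TRUE
C43-C44,TRUE
C45-C49,TRUE
C50-C50,TRUE
C51-C58,TRUE
C60-C63,TRUE
C64-C68,TRUE
C69-C72,TRUE
C73-C75,TRUE
C76-C80,TRUE
C81-C96,TRUE
C97-C97,TRUE
D00-D09,TRUE
D10-D36,TRUE
D37-D48,TRUE
D50-D53,TRUE
D55-D59,TRUE
D60-D64,TRUE
D65-D69,TRUE
D70-D77,TRUE
D80-D89,TRUE
E00-E07,TRUE
E10-E14,TRUE
E15-E16,TRUE
E20-E35,TRUE
E40-E46,TRUE
E50-E64,TRUE
E65-E68,TRUE
E70-E90,TRUE
F00-F09,TRUE
F10-F19,TRUE
F20-F29,TRUE
F30-F39,TRUE
F40-F48,TRUE
F50-F59,TRUE
F60-F69,TRUE
F70-F79,TRUE
F80-F89,TRUE
F90-F98,TRUE
F99-F99,TRUE
G00-G09,TRUE
G10-G14,TRUE
G20-G26,TRUE
G30-G32,TRUE
G35-G37,TRUE
G40-G47,TRUE
G50-G59,TRUE
G60-G64,TRUE
G70-G73,TRUE
G80-G83,TRUE
G90-G99,TRUE
H00-H06,TRUE
H10-H13,TRUE
H15-H22,TRUE
H25-H28,TRUE
H30-H36,TRUE
H40-H42,TRUE
H43-H45,TRUE
H46-H48,TRUE
H49-H52,TRUE
H53-H54,TRUE
H55-H59,TRUE
H60-H62,TRUE
H65-H75,TRUE
H80-H83,TRUE
H90-H95,TRUE
I00-I02,TRUE
I05-I09,TRUE
I10-I15,TRUE
I20-I25,TRUE
I26-I28,TRUE
I30-I52,TRUE
I60-I69,TRUE
I70-I79,TRUE
I80-I89,TRUE
I95-I99,TRUE
J00-J06,TRUE
J09-J18,TRUE
J20-J22,TRUE
J30-J39,TRUE
J40-J47,TRUE
J60-J70,TRUE
J80-J84,TRUE
J85-J86,TRUE
J90-J94,TRUE
J95-J99,TRUE
K00-K14,TRUE
K20-K31,TRUE
K35-K38,TRUE
K40-K46,TRUE
K50-K52,TRUE
K55-K64,TRUE
K65-K67,TRUE
K70-K77,TRUE
K80-K87,TRUE
K90-K93,TRUE
L00-L08,TRUE
L10-L14,TRUE
L20-L30,TRUE
L40-L45,TRUE
L50-L54,TRUE
L55-L59,TRUE
L60-L75,TRUE
L80-L99,TRUE
M00-M03,TRUE
M05-M14,TRUE
M15-M19,TRUE
M20-M25,TRUE
M30-M36,TRUE
M40-M43,TRUE
M45-M49,TRUE
M50-M54,TRUE
M60-M63,TRUE
M65-M68,TRUE
M70-M79,TRUE
M80-M85,TRUE
M86-M90,TRUE
M91-M94,TRUE
M95-M99,TRUE
N00-N08,TRUE
N10-N16,TRUE
N17-N19,TRUE
N20-N23,TRUE
N25-N29,TRUE
N30-N39,TRUE
N40-N51,TRUE
N60-N64,TRUE
N70-N77,TRUE
N80-N98,TRUE
N99-N99,TRUE
O00-O08,TRUE
O10-O16,TRUE
O20-O29,TRUE
O30-O48,TRUE
O60-O75,TRUE
O80-O84,TRUE
O85-O92,TRUE
O94-O99,TRUE
P00-P04,TRUE
P05-P08,TRUE
P10-P15,TRUE
P20-P29,TRUE
P35-P39,TRUE
P50-P61,TRUE
P70-P74,TRUE
P80-P83,TRUE
P90-P96,TRUE
Q00-Q07,TRUE
Q10-Q18,TRUE
Q20-Q28,TRUE
Q30-Q34,TRUE
Q35-Q37,TRUE
Q38-Q45,TRUE
Q50-Q56,TRUE
Q60-Q64,TRUE
Q65-Q79,TRUE
Q80-Q89,TRUE
Q90-Q99,TRUE
S00-S09,TRUE
S10-S19,TRUE
S20-S29,TRUE
S30-S39,TRUE
S40-S49,TRUE
S50-S59,TRUE
S60-S69,TRUE
S70-S79,TRUE
S80-S89,TRUE
S90-S99,TRUE
T00-T07,TRUE
T08-T14,TRUE
T15-T19,TRUE
T20-T25,TRUE
T26-T28,TRUE
T29-T32,TRUE
T33-T35,TRUE
T36-T50,TRUE
T51-T65,TRUE
T66-T78,TRUE
T79-T79,TRUE
T80-T88,TRUE
T90-T98,TRUE
R00-R99,FALSE
U00-U99,FALSE
V01-Y98,FALSE
Z00-Z99,FALSE
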