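taxon,specimen,element,observer,section,count
Morganucodon,NHMUK PV M 95790,i4,published,1,7
Morganucodon,NHMUK PV M 95790,c,published,1,7
Morganucodon,NHMUK PV M 95790,p1,published,1,8
Morganucodon,NHMUK PV M 95790,p2,published,1,8
Morganucodon,NHMUK PV M 95790,p3,published,1,8
Morganucodon,NHMUK PV M 96413,p3,published,1,5
Morganucodon,NHMUK PV M 96413,p4,published,1,5
Morganucodon,NHMUK PV M 96413,m1,published,1,5
Morganucodon,NHMUK PV M 96413,Dentary,published,1,5
Morganucodon,NHMUK PV M 96396,p4,published,1,4
Morganucodon,NHMUK PV M 96396,m1,published,1,4
Morganucodon,NHMUK PV M 96396,m2,published,1,4
Morganucodon,NHMUK PV M 96396,m3,published,1,3
Morganucodon,NHMUK PV M 96396,Dentary,published,1,4
Morganucodon,NHMUK PV M 95809,m1,published,1,3
Morganucodon,NHMUK PV M 95809,m2,published,1,3
Morganucodon,NHMUK PV M 104128,m1,published,1,5
Morganucodon,NHMUK PV M 104128,m2,published,1,5
Morganucodon,NHMUK PV M 96441,m1,published,1,5
Morganucodon,NHMUK PV M 96441,m2,published,1,5
Morganucodon,NHMUK PV M 104130,m1,published,1,5
Morganucodon,NHMUK PV M 104130,m2,published,1,5
Morganucodon,NHMUK PV M 104130,m3,published,1,4
Morganucodon,NHMUK PV M 104129,m1,published,1,9
Morganucodon,NHMUK PV M 104129,m2,published,1,9
Morganucodon,NHMUK PV M 104129,m3,published,1,8
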